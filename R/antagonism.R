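# Schild analysis of competitive antagonism.
#
# A competitive antagonist at fixed concentration B multiplies the
# agonist's apparent EC50 by the Gaddum factor (1 + B/KB). The dose
# ratio DR = EC50(+antagonist)/EC50(control) therefore satisfies
# log10(DR - 1) = log10(B) - log10(KB): a line of slope 1 whose
# x-intercept is log10(KB). The Schild regression fits that line; a
# slope near 1 supports simple competition, and the x-intercept gives
# pA2 (A2 in concentration units).

#' Dose ratio from paired logistic fits
#'
#' @param fit_with a converged [LogisticFit-class] obtained in the
#'   presence of the antagonist
#' @param fit_control the matched control fit (same agonist, receptor)
#' @param antagonist_conc_M the fixed antagonist concentration, molar
#' @return a one-row data.frame (a Schild point) with columns
#'   \code{antagonist_conc_M}, \code{dose_ratio} and \code{usable}
#'   (FALSE when the dose ratio is <= 1 and cannot enter the regression)
#' @examples
#' ctl <- logisticFit(ec50_nM = 0.16)
#' shifted <- logisticFit(ec50_nM = 0.48)
#' doseRatio(shifted, ctl, 1e-7)
#' @export
doseRatio <- function(fit_with, fit_control, antagonist_conc_M) {
  stopifnot(is(fit_with, "LogisticFit"), is(fit_control, "LogisticFit"))
  if (!fit_with@converged || !fit_control@converged)
    stop("dose ratios require converged fits")
  same_or_na <- function(a, b) is.na(a) || is.na(b) || a == b
  if (!same_or_na(fit_with@ligand_id, fit_control@ligand_id) ||
      !same_or_na(fit_with@receptor_id, fit_control@receptor_id))
    stop("mismatched assay metadata: fits are for different ",
         "agonist/receptor pairings")
  .assertScalar(antagonist_conc_M, "antagonist_conc_M", nonneg = TRUE)
  dr <- fit_with@ec50_nM / fit_control@ec50_nM
  data.frame(antagonist_conc_M = antagonist_conc_M, dose_ratio = dr,
             usable = dr > 1)
}

#' Schild regression
#'
#' Ordinary least squares of log10(DR - 1) on log10(antagonist
#' concentration in M) over all points with dose ratio > 1. Points with
#' DR <= 1 carry no information about the antagonist and are excluded
#' with a warning. The x-intercept of the fitted line gives pA2 and its
#' concentration-scale equivalent A2 = 10^(9 - pA2) nM. With exactly two
#' usable points the line is exact and the slope SE is NA.
#'
#' @param points a data.frame of Schild points as produced by
#'   [doseRatio()] (columns \code{antagonist_conc_M}, \code{dose_ratio})
#' @return a [SchildFit-class]
#' @examples
#' pts <- rbind(
#'   data.frame(antagonist_conc_M = 1e-7, dose_ratio = 3),
#'   data.frame(antagonist_conc_M = 1e-6, dose_ratio = 21))
#' schildRegression(pts) # slope 1, A2 = 50 nM
#' @export
schildRegression <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("antagonist_conc_M", "dose_ratio") %in% names(points)))
  usable <- points$dose_ratio > 1 & points$antagonist_conc_M > 0
  n_excl <- sum(!usable)
  if (n_excl > 0)
    warning(n_excl, " Schild point(s) excluded (DR_LE_1): dose ratio <= 1",
            call. = FALSE)
  if (sum(usable) < 2)
    stop("no usable Schild points: need >= 2 points with dose ratio > 1")
  x <- log10(points$antagonist_conc_M[usable])
  y <- log10(points$dose_ratio[usable] - 1)
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  slope <- unname(cf[2]); intercept <- unname(cf[1])
  n_use <- sum(usable)
  sse <- sum(stats::resid(fit)^2)
  sst <- sum((y - mean(y))^2)
  # closed-form OLS quantities (avoids summary.lm's perfect-fit warning,
  # which is the expected case for exact Gaddum data)
  se_slope <- if (n_use > 2) {
    sqrt(sse / (n_use - 2) / sum((x - mean(x))^2))
  } else {
    NA_real_   # two points define an exact line; the SE is undefined
  }
  r2 <- if (sst > 0) 1 - sse / sst else 1
  pa2 <- intercept / slope        # x-intercept is -pA2 on the log10 M axis
  new("SchildFit", slope = slope, se_slope = se_slope, pa2 = pa2,
      a2_nM = 10^(9 - pa2), r2 = r2, n_points = as.integer(sum(usable)),
      n_excluded = as.integer(n_excl))
}
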