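# Three-parameter logistic fitting with a fixed Hill slope.
#
# With the Hill slope fixed at +1 (activation) or -1 (inhibition) the
# model  y = basal + span * f(c; EC50)  is linear in (basal, span) for a
# given pEC50, so the sum of squares can be profiled down to a 1-D
# problem in pEC50. A deterministic grid search over the tested
# concentration range (extended one log unit each way) locates the
# basin; stats::optimize refines it; minpack.lm::nlsLM then polishes all
# three parameters jointly and supplies standard errors.

.logisticFraction <- function(conc_M, pec50, hill) {
  e <- 10^(-pec50)
  if (hill > 0) conc_M / (conc_M + e) else e / (conc_M + e)
}

.profileSSE <- function(pec50, conc, y, hill) {
  x <- .logisticFraction(conc, pec50, hill)
  f <- stats::lm.fit(cbind(1, x), y)
  sum(f$residuals^2)
}

# Core fixed-Hill logistic fit on (conc in M, response). Returns the raw
# pieces; callers wrap them into LogisticFit / EquilibriumResult.
.fitFixedHillLogistic <- function(conc, y, hill) {
  pos <- conc[conc > 0]
  pmin_grid <- -log10(max(pos)) - 1
  pmax_grid <- -log10(min(pos)) + 1
  grid <- seq(pmin_grid, pmax_grid, by = 0.1)
  sse_grid <- vapply(grid, .profileSSE, numeric(1), conc = conc, y = y,
                     hill = hill)
  p0 <- grid[which.min(sse_grid)]          # first minimum wins: deterministic
  opt <- stats::optimize(.profileSSE, interval = c(p0 - 0.2, p0 + 0.2),
                         conc = conc, y = y, hill = hill, tol = 1e-8)
  p_hat <- opt$minimum
  lin <- stats::lm.fit(cbind(1, .logisticFraction(conc, p_hat, hill)), y)
  basal <- unname(lin$coefficients[1]); span <- unname(lin$coefficients[2])

  df <- data.frame(conc = conc, y = y)
  fml <- if (hill > 0) {
    y ~ basal + span * conc / (conc + 10^(-pec50))
  } else {
    y ~ basal + span * 10^(-pec50) / (conc + 10^(-pec50))
  }
  nls_fit <- tryCatch(
    minpack.lm::nlsLM(fml, data = df,
                      start = list(basal = basal, span = span, pec50 = p_hat),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  converged <- FALSE
  se_pec50 <- NA_real_
  sse <- opt$objective
  if (!is.null(nls_fit)) {
    cf <- stats::coef(nls_fit)
    sse_nls <- sum(stats::resid(nls_fit)^2)
    if (sse_nls <= sse + 1e-12) {        # accept only a real improvement
      basal <- cf[["basal"]]; span <- cf[["span"]]; p_hat <- cf[["pec50"]]
      sse <- sse_nls
      converged <- isTRUE(nls_fit$convInfo$isConv)
      se_pec50 <- tryCatch(summary(nls_fit)$coefficients["pec50", 2],
                           error = function(e) NA_real_)
    }
  }
  n <- length(y)
  resid_sd <- sqrt(sse / max(1, n - 3))
  list(pec50 = unname(p_hat), basal = unname(basal), span = unname(span),
       sse = unname(sse), se_pec50 = unname(se_pec50),
       resid_sd = resid_sd, converged = converged, n = n,
       tested_range = c(-log10(max(pos)), -log10(min(pos))))
}

#' Fit a three-parameter logistic with fixed Hill slope
#'
#' Fits response = basal + span * A/(A + EC50) (activation, Hill +1) or
#' basal + span * IC50/(A + IC50) (inhibition, Hill -1) by least squares,
#' parameterized in pEC50. Zero-dose wells inform the baseline but never
#' enter a log-concentration axis (the model is evaluated on the linear
#' concentration scale, where zero is a valid input). A curve is declared
#' non-saturating (\code{isSaturating(fit) == FALSE}, reported as N.A.)
#' when the fitted span is below three residual standard deviations or
#' the midpoint falls outside the tested concentration range.
#'
#' @param curve a [DoseResponseCurve-class]
#' @param mode "activation" (Hill +1) or "inhibition" (Hill -1)
#' @return a [LogisticFit-class]
#' @examples
#' fp <- FunctionalParams(emax_frac = 1, ec50_nM = 0.16, noise_cv = 0)
#' fit <- fitLogistic(simulateDoseResponse(fp, 10^seq(-12, -7, 0.5)))
#' pEC50(fit) # 9.8
#' @export
fitLogistic <- function(curve, mode = c("activation", "inhibition")) {
  stopifnot(is(curve, "DoseResponseCurve"))
  mode <- match.arg(mode)
  hill <- if (mode == "activation") 1 else -1
  conc <- curve@conc; y <- curve@response
  if (length(unique(conc[conc > 0])) < 4)
    stop("at least 4 distinct positive concentrations are required")
  if (diff(range(y)) == 0)
    stop("all responses are equal: degenerate span, nothing to fit")
  f <- .fitFixedHillLogistic(conc, y, hill)
  na_call <- abs(f$span) < 3 * f$resid_sd ||
    f$pec50 < f$tested_range[1] || f$pec50 > f$tested_range[2]
  new("LogisticFit", pec50 = f$pec50, ec50_nM = 10^(9 - f$pec50),
      basal = f$basal, emax = f$span, hill = hill, sse = f$sse,
      se_pec50 = f$se_pec50, residual_sd = f$resid_sd,
      converged = f$converged, na_call = na_call,
      n_points = as.integer(f$n), ligand_id = curve@ligand_id,
      receptor_id = curve@receptor_id)
}

#' Normalize a dose-response curve to a reference agonist response
#'
#' Rescales raw signals to percent of a reference agonist:
#' 100 (raw - basal) / (reference - basal). Used to make curves from
#' different plates comparable (inter-assay variation).
#'
#' @param curve a [DoseResponseCurve-class] with raw signals
#' @param reference_response signal at the saturating reference-agonist
#'   concentration; must exceed the basal
#' @param basal assay baseline signal; defaults to the mean of the
#'   zero-dose wells when present, otherwise 0
#' @return a [DoseResponseCurve-class] on the percent scale
#' @export
normalizeToReference <- function(curve, reference_response, basal = NULL) {
  stopifnot(is(curve, "DoseResponseCurve"))
  if (is.null(basal)) {
    zero <- curve@response[curve@conc == 0]
    basal <- if (length(zero)) mean(zero) else 0
  }
  if (reference_response <= basal)
    stop("reference response must exceed the assay basal")
  DoseResponseCurve(conc = curve@conc,
                    response = 100 * (curve@response - basal) /
                      (reference_response - basal),
                    replicate = curve@replicate,
                    ligand_id = curve@ligand_id,
                    receptor_id = curve@receptor_id)
}

#' BRET ratio (acceptor / donor)
#'
#' The resonance-energy-transfer signal is the acceptor (YFP) channel
#' divided by the donor (RLUC) channel.
#'
#' @param acceptor acceptor-channel counts
#' @param donor donor-channel counts (> 0)
#' @return the dimensionless ratio, vectorized
#' @examples
#' bretRatio(200, 100) # 2
#' @export
bretRatio <- function(acceptor, donor) {
  if (any(donor <= 0)) stop("donor counts must be > 0")
  acceptor / donor
}

#' Fold change in potency between two logistic fits
#'
#' Returns EC50(a) / EC50(b); values above 1 mean ligand a is less potent
#' than ligand b.
#'
#' @param fit_a,fit_b converged [LogisticFit-class] objects
#' @return the dimensionless fold change
#' @examples
#' # EC50 0.44 nM vs 0.16 nM: 2.8-fold decreased potency
#' @export
potencyShift <- function(fit_a, fit_b) {
  stopifnot(is(fit_a, "LogisticFit"), is(fit_b, "LogisticFit"))
  if (!fit_a@converged || !fit_b@converged)
    stop("potency shift requires converged fits")
  fit_a@ec50_nM / fit_b@ec50_nM
}

#' Construct a LogisticFit from known parameters
#'
#' Builds a fit object directly from reported parameters (e.g. a
#' published potency table) so that downstream operations such as
#' [potencyShift()] and [doseRatio()] can be applied to literature
#' values.
#'
#' @param pec50 -log10(EC50 in M); alternatively supply \code{ec50_nM}
#' @param ec50_nM EC50 in nM (used when \code{pec50} is missing)
#' @param basal,emax,hill,se_pec50 optional parameters
#' @param ligand_id,receptor_id assay labels
#' @return a [LogisticFit-class] flagged as converged
#' @export
logisticFit <- function(pec50 = NULL, ec50_nM = NULL, basal = 0, emax = 100,
                        hill = 1, se_pec50 = NA_real_,
                        ligand_id = NA_character_,
                        receptor_id = NA_character_) {
  if (is.null(pec50)) {
    if (is.null(ec50_nM)) stop("supply pec50 or ec50_nM")
    pec50 <- 9 - log10(ec50_nM)
  }
  new("LogisticFit", pec50 = pec50, ec50_nM = 10^(9 - pec50),
      basal = basal, emax = emax, hill = hill, sse = 0,
      se_pec50 = se_pec50, residual_sd = 0, converged = TRUE,
      na_call = FALSE, n_points = 0L, ligand_id = as.character(ligand_id),
      receptor_id = as.character(receptor_id))
}
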