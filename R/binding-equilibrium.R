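# Equilibrium competition-binding analysis.
#
# A homologous displacement curve (tracer displaced by its own unlabelled
# form) yields IC50 = [L] + KD, so KD = IC50 - [L] and the receptor
# density Bmax = B0 IC50 / [L] with B0 the total specific binding at zero
# competitor. A heterologous curve yields the competitor's inhibition
# constant through the Cheng-Prusoff correction Ki = IC50/(1 + [L]/KD).

#' Specific binding: total minus nonspecific
#'
#' Elementwise difference of matched total and nonspecific count series;
#' negative differences (counting noise below background) are clamped to
#' zero and reported in a single warning (reason code
#' NEG_SPECIFIC_CLAMPED).
#'
#' @param total total bound counts, CPM
#' @param nonspecific matched nonspecific counts, CPM
#' @return the specific binding series, CPM (>= 0)
#' @examples
#' specificBinding(c(1000, 200), c(200, 200)) # 800 0
#' @export
specificBinding <- function(total, nonspecific) {
  if (length(total) != length(nonspecific))
    stop("total and nonspecific series must have equal length")
  d <- total - nonspecific
  n_clamped <- sum(d < 0)
  if (n_clamped > 0)
    warning(n_clamped, " point(s) clamped to 0 (NEG_SPECIFIC_CLAMPED): ",
            "total below nonspecific background", call. = FALSE)
  pmax(d, 0)
}

#' Fit a competition-binding curve (pIC50 and B0)
#'
#' Fits the specific binding (total minus nonspecific) against competitor
#' concentration with a three-parameter logistic, Hill slope fixed at -1.
#' B0, the total specific binding at zero competitor, is taken as the
#' fitted top of the logistic rather than the raw zero-competitor wells,
#' to reduce noise sensitivity. A curve whose fitted span is below three
#' residual standard deviations is reported as "no binding detected"
#' (\code{object@nb == TRUE}), with no numeric IC50.
#'
#' @param curve a [CompetitionCurve-class]; needs >= 4 competitor
#'   concentrations spanning >= 2 log units
#' @return an [EquilibriumResult-class] with pic50, ic50_nM and b0_cpm
#'   set (derived constants are filled in by [analyzeCompetition()])
#' @export
fitCompetition <- function(curve) {
  stopifnot(is(curve, "CompetitionCurve"))
  conc <- curve@competitor_conc
  pos <- unique(conc[conc > 0])
  if (length(pos) < 4 || log10(max(pos) / min(pos)) < 2)
    stop("need >= 4 competitor concentrations spanning >= 2 log units")
  spec <- specificBinding(curve@bound, curve@nonspecific)
  nb_result <- function() new("EquilibriumResult",
    pic50 = NA_real_, se_pic50 = NA_real_, ic50_nM = NA_real_,
    b0_cpm = NA_real_, bmax_cpm = NA_real_, kd_nM = NA_real_,
    ki_nM = NA_real_, mode = "homologous", nb = TRUE,
    n_points = length(spec))
  if (diff(range(spec)) == 0) return(nb_result())
  f <- .fitFixedHillLogistic(conc, spec, hill = -1)
  if (abs(f$span) < 3 * f$resid_sd) return(nb_result())   # N.B.: flat curve
  b0 <- f$basal + f$span                                  # fitted top
  new("EquilibriumResult", pic50 = f$pec50,
      se_pic50 = f$se_pec50, ic50_nM = 10^(9 - f$pec50), b0_cpm = b0,
      bmax_cpm = NA_real_, kd_nM = NA_real_, ki_nM = NA_real_,
      mode = "homologous", nb = FALSE, n_points = as.integer(f$n))
}

#' Receptor density from a homologous competition curve
#'
#' Bmax = B0 IC50 / L, where B0 is the total specific binding (CPM) at
#' zero competitor and L the tracer concentration (nM).
#'
#' @param b0_cpm total specific binding at zero competitor, CPM
#' @param ic50_nM half-maximal displacement concentration, nM
#' @param L_nM tracer concentration, nM
#' @return Bmax in CPM
#' @examples
#' bmaxHomologous(1000, 60, 0.06) # 1e6
#' @export
bmaxHomologous <- function(b0_cpm, ic50_nM, L_nM) {
  .assertScalar(b0_cpm, "b0_cpm", positive = TRUE)
  .assertScalar(ic50_nM, "ic50_nM", positive = TRUE)
  .assertScalar(L_nM, "L_nM", positive = TRUE)
  b0_cpm * ic50_nM / L_nM
}

#' Equilibrium dissociation constant from a homologous competition curve
#'
#' KD = IC50 - L. An IC50 below the tracer concentration is physically
#' impossible for homologous displacement and signals an assay
#' inconsistency.
#'
#' @param ic50_nM half-maximal displacement concentration, nM
#' @param L_nM tracer concentration, nM
#' @return KD in nM
#' @examples
#' kdHomologous(59.36, 0.06) # 59.3
#' @export
kdHomologous <- function(ic50_nM, L_nM) {
  .assertScalar(ic50_nM, "ic50_nM", positive = TRUE)
  .assertScalar(L_nM, "L_nM", positive = TRUE)
  if (ic50_nM < L_nM)
    stop("IC50 below tracer concentration: homologous assay inconsistency")
  ic50_nM - L_nM
}

#' Cheng-Prusoff inhibition constant
#'
#' Ki = IC50 / (1 + L/KD), converting the half-maximal displacement
#' concentration of a heterologous competitor into its receptor affinity,
#' given the tracer concentration L and the tracer's own KD.
#'
#' @param ic50_nM half-maximal displacement concentration, nM
#' @param L_nM tracer concentration, nM (>= 0)
#' @param kd_nM tracer equilibrium dissociation constant, nM (> 0)
#' @return Ki in nM
#' @examples
#' kiChengPrusoff(126, 0.06, 59.3) # ~125.9
#' @export
kiChengPrusoff <- function(ic50_nM, L_nM, kd_nM) {
  .assertScalar(ic50_nM, "ic50_nM", positive = TRUE)
  .assertScalar(L_nM, "L_nM", nonneg = TRUE)
  .assertScalar(kd_nM, "kd_nM", positive = TRUE)
  ic50_nM / (1 + L_nM / kd_nM)
}

#' Convert a CPM-scale Bmax to fmol per 1e5 cells
#'
#' @param bmax_cpm receptor density, CPM
#' @param specific_activity_cpm_per_fmol counter efficiency times specific
#'   radioactivity, CPM per fmol
#' @param n_cells number of cells in the assayed sample
#' @return Bmax in fmol per 1e5 cells
#' @export
bmaxToFmolPer1e5Cells <- function(bmax_cpm, specific_activity_cpm_per_fmol,
                                  n_cells) {
  .assertScalar(bmax_cpm, "bmax_cpm", positive = TRUE)
  .assertScalar(specific_activity_cpm_per_fmol,
                "specific_activity_cpm_per_fmol", positive = TRUE)
  .assertScalar(n_cells, "n_cells", positive = TRUE)
  bmax_cpm / specific_activity_cpm_per_fmol / (n_cells / 1e5)
}

#' Full equilibrium competition-binding analysis
#'
#' Fits the displacement curve ([fitCompetition()]) and derives the
#' mode-specific constants: homologous mode gives KD = IC50 - L and
#' Bmax = B0 IC50 / L; heterologous mode gives the Cheng-Prusoff Ki
#' (which requires the tracer's KD). The mode is declared by the caller,
#' not inferred from the data.
#'
#' @param curve a [CompetitionCurve-class]
#' @param mode "homologous" or "heterologous"
#' @param tracer_kd_nM tracer KD, nM; required for heterologous mode
#' @return an [EquilibriumResult-class]
#' @examples
#' sys <- SystemParams(bmax_cpm = 5e5, kd_nM = 40, noise_cv = 0, seed = 1L)
#' cc <- simulateCompetition(sys, L = 0.05,
#'                           competitor_concs = c(0, 10^seq(-10, -5, 0.5)))
#' res <- analyzeCompetition(cc, "homologous")
#' kdNM(res) # ~40
#' @export
analyzeCompetition <- function(curve, mode = c("homologous", "heterologous"),
                               tracer_kd_nM = NULL) {
  mode <- match.arg(mode)
  res <- fitCompetition(curve)
  res@mode <- mode
  if (res@nb) return(res)
  L <- curve@tracer_conc_L
  if (mode == "homologous") {
    res@kd_nM <- kdHomologous(res@ic50_nM, L)
    res@bmax_cpm <- bmaxHomologous(res@b0_cpm, res@ic50_nM, L)
  } else {
    if (is.null(tracer_kd_nM))
      stop("heterologous mode requires the tracer KD (tracer_kd_nM)")
    res@ki_nM <- kiChengPrusoff(res@ic50_nM, L, tracer_kd_nM)
  }
  validObject(res)
  res
}
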