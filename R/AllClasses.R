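#' @import methods
NULL

.scalarNum <- function(x) is.numeric(x) && length(x) == 1L
.scalarChr <- function(x) is.character(x) && length(x) == 1L

#' Ground-truth parameters of a mass-action binding system
#'
#' Holds the receptor/ligand parameters that drive the synthetic-assay
#' generator: maximal specific binding (\code{bmax_cpm}, CPM), association
#' rate constant \code{kon} (nM^-1 min^-1), dissociation rate constant
#' \code{koff} (min^-1), equilibrium dissociation constant \code{kd_nM}
#' (nM; equal to koff/kon when kinetic rates are given), nonspecific
#' binding as a fraction of total added counts, the coefficient of
#' variation of the Gaussian measurement noise, and an RNG seed.
#'
#' @slot bmax_cpm maximal specific binding, CPM (> 0)
#' @slot kon association rate constant, nM^-1 min^-1 (NA if unknown)
#' @slot koff dissociation rate constant, min^-1 (NA if unknown)
#' @slot kd_nM equilibrium dissociation constant, nM
#' @slot ns_fraction nonspecific binding fraction of added counts, in [0, 1)
#' @slot noise_cv coefficient of variation of measurement noise (>= 0)
#' @slot seed integer RNG seed (NA for unseeded)
#' @seealso [SystemParams()] for the user-facing constructor
#' @exportClass SystemParams
setClass("SystemParams", representation(
  bmax_cpm = "numeric", kon = "numeric", koff = "numeric", kd_nM = "numeric",
  ns_fraction = "numeric", noise_cv = "numeric", seed = "integer"
))

setValidity("SystemParams", function(object) {
  msg <- character()
  if (!.scalarNum(object@bmax_cpm) || !is.finite(object@bmax_cpm) ||
      object@bmax_cpm <= 0)
    msg <- c(msg, "bmax_cpm must be a positive number")
  if (!.scalarNum(object@kd_nM) || is.na(object@kd_nM) || object@kd_nM <= 0)
    msg <- c(msg, "kd_nM must be a positive number")
  if (!is.na(object@kon) && object@kon <= 0)
    msg <- c(msg, "kon must be > 0 when supplied")
  if (!is.na(object@koff) && object@koff <= 0)
    msg <- c(msg, "koff must be > 0 when supplied")
  if (!is.na(object@kon) && !is.na(object@koff)) {
    kd <- object@koff / object@kon
    if (abs(kd - object@kd_nM) > 1e-9 * kd)
      msg <- c(msg, "kd_nM must equal koff/kon (within 1e-9 relative)")
  }
  if (object@ns_fraction < 0 || object@ns_fraction >= 1)
    msg <- c(msg, "ns_fraction must lie in [0, 1)")
  if (object@noise_cv < 0) msg <- c(msg, "noise_cv must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Ground-truth parameters of a functional (dose-response) system
#'
#' Parameters of the logistic response the simulator emulates: baseline
#' response, maximal effect as a fraction of the reference full agonist,
#' half-maximal agonist concentration, and (optionally) the antagonist
#' equilibrium constant KB that produces the Gaddum rightward shift
#' EC50 -> EC50 (1 + B/KB) under a fixed antagonist concentration B.
#'
#' @slot basal baseline response (response units)
#' @slot emax_frac maximal effect as fraction of reference agonist (0-1.1)
#' @slot ec50_nM half-maximal agonist concentration, nM (> 0)
#' @slot kb_nM antagonist equilibrium constant, nM (NA when no antagonist)
#' @slot noise_cv coefficient of variation of measurement noise (>= 0)
#' @slot seed integer RNG seed (NA for unseeded)
#' @seealso [FunctionalParams()]
#' @exportClass FunctionalParams
setClass("FunctionalParams", representation(
  basal = "numeric", emax_frac = "numeric", ec50_nM = "numeric",
  kb_nM = "numeric", noise_cv = "numeric", seed = "integer"
))

setValidity("FunctionalParams", function(object) {
  msg <- character()
  if (!.scalarNum(object@ec50_nM) || is.na(object@ec50_nM) ||
      object@ec50_nM <= 0)
    msg <- c(msg, "ec50_nM must be a positive number")
  if (object@emax_frac < 0 || object@emax_frac > 1.1)
    msg <- c(msg, "emax_frac must lie in [0, 1.1]")
  if (!is.na(object@kb_nM) && object@kb_nM <= 0)
    msg <- c(msg, "kb_nM must be > 0 when supplied")
  if (object@noise_cv < 0) msg <- c(msg, "noise_cv must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Concentration-response data for one ligand-receptor pairing
#'
#' Tidy long-format container: one row per well. Concentrations are molar;
#' zero-dose wells are allowed and represent basal (unstimulated) wells.
#'
#' @slot ligand_id,receptor_id assay labels
#' @slot conc agonist concentration, molar (>= 0; 0 marks basal wells)
#' @slot response raw signal or percent-of-reference
#' @slot replicate integer replicate index
#' @exportClass DoseResponseCurve
setClass("DoseResponseCurve", representation(
  ligand_id = "character", receptor_id = "character",
  conc = "numeric", response = "numeric", replicate = "integer"
))

setValidity("DoseResponseCurve", function(object) {
  msg <- character()
  n <- length(object@conc)
  if (length(object@response) != n || length(object@replicate) != n)
    msg <- c(msg, "conc, response and replicate must have equal length")
  if (any(!is.finite(object@response)))
    msg <- c(msg, "responses must be finite")
  if (any(!is.finite(object@conc)) || any(object@conc < 0))
    msg <- c(msg, "concentrations must be finite and >= 0")
  if (length(msg)) msg else TRUE
})

#' Three-parameter logistic fit with fixed Hill slope
#'
#' Result of fitting a concentration-response curve with a Hill slope
#' fixed at +1 (activation) or -1 (inhibition). The fit is parameterized
#' in pEC50 = -log10(EC50 in M); \code{ec50_nM} always equals
#' 10^(9 - pec50). \code{na_call} records the "no activation / no binding"
#' call made when the fitted span is indistinguishable from noise or the
#' midpoint falls outside the tested concentration range.
#'
#' @slot pec50 -log10(EC50 in M)
#' @slot ec50_nM EC50 (or IC50 for inhibition fits) in nM
#' @slot basal fitted baseline (response units)
#' @slot emax fitted span (top minus baseline, response units)
#' @slot hill fixed Hill slope, +1 or -1
#' @slot sse residual sum of squares
#' @slot se_pec50 standard error of pec50 (NA when unavailable)
#' @slot residual_sd residual standard deviation
#' @slot converged logical convergence flag
#' @slot na_call logical; TRUE when the curve is declared non-saturating
#' @slot n_points number of data points used
#' @slot ligand_id,receptor_id assay labels carried from the curve
#' @exportClass LogisticFit
setClass("LogisticFit", representation(
  pec50 = "numeric", ec50_nM = "numeric", basal = "numeric", emax = "numeric",
  hill = "numeric", sse = "numeric", se_pec50 = "numeric",
  residual_sd = "numeric", converged = "logical", na_call = "logical",
  n_points = "integer", ligand_id = "character", receptor_id = "character"
))

setValidity("LogisticFit", function(object) {
  msg <- character()
  if (!object@hill %in% c(-1, 1)) msg <- c(msg, "hill must be +1 or -1")
  if (is.finite(object@pec50)) {
    ec <- 10^(9 - object@pec50)
    if (abs(ec - object@ec50_nM) > 1e-6 * ec)
      msg <- c(msg, "ec50_nM must equal 10^(9 - pec50)")
  }
  if (length(msg)) msg else TRUE
})

#' Competition-binding data (radioligand displacement)
#'
#' One row per well: total bound counts at increasing competitor
#' concentration with a fixed low tracer concentration. Zero-competitor
#' wells define B0. A matched nonspecific channel (mock-transfected
#' control) is carried alongside for specific-binding subtraction.
#'
#' @slot radioligand_id,competitor_id,receptor_id assay labels
#' @slot tracer_conc_L radioligand concentration, nM (> 0)
#' @slot competitor_conc competitor concentration, molar (>= 0)
#' @slot bound total bound counts, CPM (>= 0)
#' @slot nonspecific matched nonspecific counts, CPM
#' @slot replicate integer replicate index
#' @exportClass CompetitionCurve
setClass("CompetitionCurve", representation(
  radioligand_id = "character", competitor_id = "character",
  receptor_id = "character", tracer_conc_L = "numeric",
  competitor_conc = "numeric", bound = "numeric", nonspecific = "numeric",
  replicate = "integer"
))

setValidity("CompetitionCurve", function(object) {
  msg <- character()
  if (!.scalarNum(object@tracer_conc_L) || object@tracer_conc_L <= 0)
    msg <- c(msg, "tracer_conc_L must be a single positive number (nM)")
  n <- length(object@competitor_conc)
  if (length(object@bound) != n || length(object@nonspecific) != n ||
      length(object@replicate) != n)
    msg <- c(msg, "competitor_conc, bound, nonspecific, replicate must match")
  if (any(object@competitor_conc < 0))
    msg <- c(msg, "competitor concentrations must be >= 0")
  if (any(object@bound < 0)) msg <- c(msg, "bound counts must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Result of equilibrium competition-binding analysis
#'
#' Carries the logistic IC50 fit plus the derived quantities: Bmax from
#' the homologous relation Bmax = B0 IC50 / L, KD = IC50 - L (homologous
#' mode) or the Cheng-Prusoff Ki = IC50 / (1 + L/KD) (heterologous mode).
#' Exactly one of \code{kd_nM}/\code{ki_nM} is set per mode. \code{nb}
#' flags the "no binding detected" call for flat curves.
#'
#' @slot pic50 -log10(IC50 in M)
#' @slot se_pic50 its standard error
#' @slot ic50_nM IC50 in nM
#' @slot b0_cpm total specific binding at zero competitor (fitted top)
#' @slot bmax_cpm receptor density in CPM (homologous mode, else NA)
#' @slot kd_nM equilibrium dissociation constant, nM (homologous mode)
#' @slot ki_nM inhibition constant, nM (heterologous mode)
#' @slot mode "homologous" or "heterologous"
#' @slot nb logical; TRUE when no displacement was detected
#' @slot n_points number of data points used
#' @exportClass EquilibriumResult
setClass("EquilibriumResult", representation(
  pic50 = "numeric", se_pic50 = "numeric", ic50_nM = "numeric",
  b0_cpm = "numeric", bmax_cpm = "numeric", kd_nM = "numeric",
  ki_nM = "numeric", mode = "character", nb = "logical",
  n_points = "integer"
))

setValidity("EquilibriumResult", function(object) {
  msg <- character()
  if (!object@mode %in% c("homologous", "heterologous"))
    msg <- c(msg, "mode must be 'homologous' or 'heterologous'")
  if (!object@nb && !is.na(object@kd_nM) && !is.na(object@ki_nM))
    msg <- c(msg, "at most one of kd_nM and ki_nM may be set")
  if (length(msg)) msg else TRUE
})

#' Timed radioligand binding trace
#'
#' Association or dissociation time course with paired total and
#' nonspecific channels; specific binding is total minus nonspecific,
#' clamped at zero. Times are minutes, strictly increasing within each
#' replicate.
#'
#' @slot time minutes
#' @slot total total bound counts, CPM
#' @slot nonspecific nonspecific (mock-transfected) counts, CPM
#' @slot specific total minus nonspecific, clamped at 0
#' @slot tracer_conc_L radioligand concentration, nM
#' @slot phase "association" or "dissociation"
#' @slot replicate integer replicate index
#' @exportClass KineticTrace
setClass("KineticTrace", representation(
  time = "numeric", total = "numeric", nonspecific = "numeric",
  specific = "numeric", tracer_conc_L = "numeric", phase = "character",
  replicate = "integer"
))

setValidity("KineticTrace", function(object) {
  msg <- character()
  if (!object@phase %in% c("association", "dissociation"))
    msg <- c(msg, "phase must be 'association' or 'dissociation'")
  if (!.scalarNum(object@tracer_conc_L) || object@tracer_conc_L <= 0)
    msg <- c(msg, "tracer_conc_L must be a single positive number (nM)")
  n <- length(object@time)
  if (length(object@total) != n || length(object@nonspecific) != n ||
      length(object@specific) != n || length(object@replicate) != n)
    msg <- c(msg, "time, total, nonspecific, specific, replicate must match")
  for (r in unique(object@replicate)) {
    tt <- object@time[object@replicate == r]
    if (any(diff(tt) <= 0)) {
      msg <- c(msg, "times must be strictly increasing within a replicate")
      break
    }
  }
  sp <- pmax(object@total - object@nonspecific, 0)
  if (any(abs(sp - object@specific) > 1e-8 * pmax(1, abs(sp))))
    msg <- c(msg, "specific must equal max(total - nonspecific, 0)")
  if (length(msg)) msg else TRUE
})

#' One-phase exponential fit of a kinetic trace
#'
#' For association: specific(t) = amplitude (1 - exp(-rate t)), rate =
#' kobs. For dissociation: specific(t) = amplitude exp(-rate t) (floor
#' fixed at 0 by default), rate = koff.
#'
#' @slot phase "association" or "dissociation"
#' @slot rate fitted rate constant, min^-1
#' @slot se_rate its standard error
#' @slot amplitude fitted plateau (association) or starting level
#'   (dissociation), CPM
#' @slot se_amplitude its standard error
#' @slot sse residual sum of squares
#' @slot converged logical convergence flag
#' @slot n_points number of points used
#' @exportClass KineticFit
setClass("KineticFit", representation(
  phase = "character", rate = "numeric", se_rate = "numeric",
  amplitude = "numeric", se_amplitude = "numeric", sse = "numeric",
  converged = "logical", n_points = "integer"
))

setValidity("KineticFit", function(object) {
  msg <- character()
  if (!object@phase %in% c("association", "dissociation"))
    msg <- c(msg, "phase must be 'association' or 'dissociation'")
  if (is.finite(object@rate) && object@rate <= 0)
    msg <- c(msg, "fitted rate must be positive")
  if (length(msg)) msg else TRUE
})

#' Derived kinetic constants with propagated standard errors
#'
#' kon = (kobs - koff)/L and kinetic KD = koff/kon, with delta-method
#' standard errors. Internal consistency of the stored values is enforced
#' to 1e-9 relative.
#'
#' @slot kobs observed association rate, min^-1, with SE
#' @slot koff dissociation rate constant, min^-1, with SE
#' @slot kon association rate constant, nM^-1 min^-1, with SE
#' @slot kd_nM kinetic equilibrium dissociation constant, nM, with SE
#' @slot tracer_conc_L radioligand concentration used, nM, with SE
#' @slot plateau_cpm association plateau, CPM (NA when not recorded)
#' @slot se_kobs,se_koff,se_kon,se_kd,se_L standard errors
#' @exportClass KineticConstants
setClass("KineticConstants", representation(
  kobs = "numeric", se_kobs = "numeric", koff = "numeric",
  se_koff = "numeric", kon = "numeric", se_kon = "numeric",
  kd_nM = "numeric", se_kd = "numeric", tracer_conc_L = "numeric",
  se_L = "numeric", plateau_cpm = "numeric"
))

setValidity("KineticConstants", function(object) {
  msg <- character()
  if (any(c(object@kobs, object@koff, object@kon, object@kd_nM) <= 0))
    msg <- c(msg, "all rates and KD must be positive")
  kon <- (object@kobs - object@koff) / object@tracer_conc_L
  if (abs(kon - object@kon) > 1e-9 * abs(kon))
    msg <- c(msg, "kon must equal (kobs - koff)/L")
  kd <- object@koff / object@kon
  if (abs(kd - object@kd_nM) > 1e-9 * abs(kd))
    msg <- c(msg, "kd_nM must equal koff/kon")
  if (any(c(object@se_kobs, object@se_koff, object@se_L) < 0, na.rm = TRUE))
    msg <- c(msg, "standard errors must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Schild regression result
#'
#' Ordinary least squares of log10(DR - 1) on log10 antagonist
#' concentration (M). The x-intercept gives pA2 = -log10(A2 in M);
#' \code{a2_nM} always equals 10^(9 - pa2). With exactly two usable
#' points the line is exact and the slope SE is reported as NA.
#'
#' @slot slope Schild slope (1 for simple competition)
#' @slot se_slope its standard error (NA with two points)
#' @slot pa2 -log10(A2 in M)
#' @slot a2_nM antagonist apparent affinity, nM
#' @slot r2 coefficient of determination
#' @slot n_points usable points (dose ratio > 1)
#' @slot n_excluded points dropped because dose ratio <= 1
#' @exportClass SchildFit
setClass("SchildFit", representation(
  slope = "numeric", se_slope = "numeric", pa2 = "numeric",
  a2_nM = "numeric", r2 = "numeric", n_points = "integer",
  n_excluded = "integer"
))

setValidity("SchildFit", function(object) {
  msg <- character()
  if (is.finite(object@pa2)) {
    a2 <- 10^(9 - object@pa2)
    if (abs(a2 - object@a2_nM) > 1e-6 * a2)
      msg <- c(msg, "a2_nM must equal 10^(9 - pa2)")
  }
  if (length(msg)) msg else TRUE
})
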