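#' Create the ground-truth parameters of a binding system
#'
#' Either both kinetic rate constants (\code{kon}, \code{koff}) or the
#' equilibrium constant \code{kd_nM} must be supplied. When both rates are
#' given, \code{kd_nM} is derived as koff/kon (and checked for consistency
#' if also supplied).
#'
#' @param bmax_cpm maximal specific binding, CPM (> 0)
#' @param kon association rate constant, nM^-1 min^-1
#' @param koff dissociation rate constant, min^-1
#' @param kd_nM equilibrium dissociation constant, nM
#' @param ns_fraction nonspecific binding as a fraction of total added
#'   counts, in [0, 1)
#' @param noise_cv coefficient of variation of the Gaussian measurement
#'   noise applied to each counted channel
#' @param seed integer RNG seed; identical seeds give bit-identical
#'   simulated data
#' @return a [SystemParams-class] object
#' @examples
#' sys <- SystemParams(bmax_cpm = 2000, kon = 0.308, koff = 0.010)
#' kdNM(sys) # 0.0325 nM
#' @export
SystemParams <- function(bmax_cpm, kon = NA_real_, koff = NA_real_,
                         kd_nM = NA_real_, ns_fraction = 0.02,
                         noise_cv = 0.05, seed = NA_integer_) {
  if (!is.na(kon) && !is.na(koff)) {
    derived <- koff / kon
    if (!is.na(kd_nM) && abs(kd_nM - derived) > 1e-9 * derived)
      stop("supplied kd_nM is inconsistent with koff/kon")
    kd_nM <- derived
  }
  if (is.na(kd_nM))
    stop("either kd_nM or both kon and koff must be supplied")
  new("SystemParams", bmax_cpm = as.numeric(bmax_cpm),
      kon = as.numeric(kon), koff = as.numeric(koff),
      kd_nM = as.numeric(kd_nM), ns_fraction = as.numeric(ns_fraction),
      noise_cv = as.numeric(noise_cv), seed = as.integer(seed))
}

#' Create the ground-truth parameters of a dose-response system
#'
#' @param basal baseline response (response units; fraction-of-reference
#'   scale by convention, so a full agonist has \code{emax_frac = 1})
#' @param emax_frac maximal effect as a fraction of the reference full
#'   agonist (0 to 1.1)
#' @param ec50_nM half-maximal agonist concentration, nM
#' @param kb_nM antagonist equilibrium constant KB, nM; required when an
#'   antagonist concentration is passed to the simulator
#' @param noise_cv coefficient of variation of the measurement noise
#' @param seed integer RNG seed
#' @return a [FunctionalParams-class] object
#' @examples
#' fp <- FunctionalParams(emax_frac = 1, ec50_nM = 0.16, kb_nM = 51.9)
#' @export
FunctionalParams <- function(basal = 0, emax_frac = 1, ec50_nM,
                             kb_nM = NA_real_, noise_cv = 0.05,
                             seed = NA_integer_) {
  new("FunctionalParams", basal = as.numeric(basal),
      emax_frac = as.numeric(emax_frac), ec50_nM = as.numeric(ec50_nM),
      kb_nM = as.numeric(kb_nM), noise_cv = as.numeric(noise_cv),
      seed = as.integer(seed))
}

#' Build a concentration-response curve container
#'
#' @param conc agonist concentration, molar (0 allowed for basal wells)
#' @param response measured signal (raw or percent-of-reference)
#' @param replicate integer replicate index (recycled if scalar)
#' @param ligand_id,receptor_id assay labels
#' @return a [DoseResponseCurve-class] object
#' @export
DoseResponseCurve <- function(conc, response, replicate = 1L,
                              ligand_id = NA_character_,
                              receptor_id = NA_character_) {
  n <- length(conc)
  replicate <- as.integer(rep_len(replicate, n))
  new("DoseResponseCurve", ligand_id = as.character(ligand_id),
      receptor_id = as.character(receptor_id), conc = as.numeric(conc),
      response = as.numeric(response), replicate = replicate)
}

#' Build a competition-binding curve container
#'
#' @param competitor_conc competitor concentration, molar (0 = B0 wells)
#' @param bound total bound counts, CPM
#' @param nonspecific matched nonspecific counts, CPM (scalar recycled);
#'   defaults to 0 when the input is already specific binding
#' @param tracer_conc_L radioligand concentration, nM
#' @param replicate integer replicate index
#' @param radioligand_id,competitor_id,receptor_id assay labels
#' @return a [CompetitionCurve-class] object
#' @export
CompetitionCurve <- function(competitor_conc, bound, tracer_conc_L,
                             nonspecific = 0, replicate = 1L,
                             radioligand_id = NA_character_,
                             competitor_id = NA_character_,
                             receptor_id = NA_character_) {
  n <- length(competitor_conc)
  new("CompetitionCurve", radioligand_id = as.character(radioligand_id),
      competitor_id = as.character(competitor_id),
      receptor_id = as.character(receptor_id),
      tracer_conc_L = as.numeric(tracer_conc_L),
      competitor_conc = as.numeric(competitor_conc),
      bound = as.numeric(bound),
      nonspecific = as.numeric(rep_len(nonspecific, n)),
      replicate = as.integer(rep_len(replicate, n)))
}

#' Build a kinetic binding trace
#'
#' Specific binding is computed as total minus nonspecific, clamped at 0
#' (a warning reports how many points were clamped).
#'
#' @param time minutes, strictly increasing within each replicate
#' @param total total bound counts, CPM
#' @param nonspecific nonspecific (mock-transfected) counts, CPM
#' @param tracer_conc_L radioligand concentration, nM
#' @param phase "association" or "dissociation"
#' @param replicate integer replicate index
#' @return a [KineticTrace-class] object
#' @export
KineticTrace <- function(time, total, nonspecific, tracer_conc_L,
                         phase = c("association", "dissociation"),
                         replicate = 1L) {
  phase <- match.arg(phase)
  n <- length(time)
  nonspecific <- rep_len(as.numeric(nonspecific), n)
  specific <- specificBinding(as.numeric(total), nonspecific)
  new("KineticTrace", time = as.numeric(time), total = as.numeric(total),
      nonspecific = nonspecific, specific = specific,
      tracer_conc_L = as.numeric(tracer_conc_L), phase = phase,
      replicate = as.integer(rep_len(replicate, n)))
}
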