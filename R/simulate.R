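# Mass-action synthetic-assay generator.
#
# All kinetic expectations are the closed-form solutions of the two-state
# binding scheme R + L <-> RL under pseudo-first-order conditions (free
# tracer not depleted):
#   specific(t) = Beq (1 - exp(-kobs t)),  kobs = kon [L] + koff,
#   Beq = Bmax [L] / ([L] + KD).
# Nonspecific binding is a time- and competitor-independent fraction of
# the total added counts and is emitted as a separate mock-transfected
# channel. Counting noise is Gaussian with user CV, truncated at zero.

.addedCpm <- function(sys, added_cpm, L) {
  # default: the equilibrium specific binding Beq at this tracer
  # concentration is 7.5% of the added counts, the midpoint of the
  # 5-10% specific binding the assays are designed for
  if (is.null(added_cpm)) {
    sys@bmax_cpm * L / (L + sys@kd_nM) / 0.075
  } else {
    .assertScalar(added_cpm, "added_cpm", positive = TRUE)
  }
}

.depletionGuard <- function(max_specific, added_cpm) {
  if (max_specific > 0.1 * added_cpm)
    warning("bound tracer exceeds 10% of added tracer; ",
            "pseudo-first-order assumption may be violated", call. = FALSE)
}

.kineticRates <- function(sys) {
  if (is.na(sys@kon) || is.na(sys@koff))
    stop("kinetic simulation requires both kon and koff in SystemParams")
  list(kon = sys@kon, koff = sys@koff)
}

.noisyTrace <- function(sys, times, spec_mu, ns_cpm, L, phase, n_rep, seed) {
  nt <- length(times)
  .withSeed(if (is.null(seed)) sys@seed else seed, function() {
    total <- numeric(0); nonspec <- numeric(0); rep_idx <- integer(0)
    for (r in seq_len(n_rep)) {
      total <- c(total, .noisyCounts(spec_mu + ns_cpm, sys@noise_cv))
      nonspec <- c(nonspec, .noisyCounts(rep(ns_cpm, nt), sys@noise_cv))
      rep_idx <- c(rep_idx, rep(r, nt))
    }
    # clamping of noisy sub-background points is expected here, not an
    # analysis anomaly: keep the generator quiet
    suppressWarnings(
      KineticTrace(time = rep(times, n_rep), total = total,
                   nonspecific = nonspec, tracer_conc_L = L, phase = phase,
                   replicate = rep_idx))
  })
}

#' Simulate a radioligand association time course
#'
#' Expected specific binding follows Beq (1 - exp(-kobs t)) with
#' kobs = kon L + koff and Beq = Bmax L / (L + KD). Total and
#' nonspecific (mock-transfected) channels are emitted per replicate; the
#' nonspecific channel is a constant fraction of the added counts.
#'
#' @param sys a [SystemParams()] object with kinetic rates set
#' @param L tracer concentration, nM (> 0)
#' @param times sampling times in minutes, ascending, times[1] >= 0
#' @param n_rep number of replicates
#' @param added_cpm total added tracer counts per well, CPM; by default
#'   chosen so the equilibrium specific binding at this L is 7.5% of the
#'   added counts, the midpoint of the assay's 5-10% specific-binding
#'   design
#' @param seed optional RNG seed overriding the one in \code{sys}
#' @return a [KineticTrace-class] with phase "association"
#' @examples
#' sys <- SystemParams(bmax_cpm = 2000, kon = 0.308, koff = 0.010,
#'                     noise_cv = 0, seed = 1L)
#' tr <- simulateAssociation(sys, L = 0.21, times = 0:100)
#' @export
simulateAssociation <- function(sys, L, times, n_rep = 1,
                                added_cpm = NULL, seed = NULL) {
  stopifnot(is(sys, "SystemParams"))
  .assertScalar(L, "L", positive = TRUE)
  if (length(times) < 1 || any(diff(times) <= 0) || times[1] < 0)
    stop("times must be ascending and start at >= 0")
  rates <- .kineticRates(sys)
  added <- .addedCpm(sys, added_cpm, L)
  kobs <- rates$kon * L + rates$koff
  beq <- sys@bmax_cpm * L / (L + sys@kd_nM)
  .depletionGuard(beq, added)
  spec_mu <- beq * (1 - exp(-kobs * times))
  .noisyTrace(sys, times, spec_mu, sys@ns_fraction * added, L,
              "association", n_rep, seed)
}

#' Simulate a radioligand dissociation time course
#'
#' After \code{preincubation_min} minutes of association, dissociation is
#' initiated by an excess of unlabelled competitor (the chase); expected
#' specific binding then decays as B(t0) exp(-koff t). The chase must be
#' at least 100 x KD so that rebinding of the dissociated tracer is
#' negligible.
#'
#' @inheritParams simulateAssociation
#' @param preincubation_min association time before the chase, minutes
#' @param chase_nM concentration of unlabelled competitor, nM
#' @param times minutes after chase addition, ascending from >= 0
#' @return a [KineticTrace-class] with phase "dissociation"
#' @export
simulateDissociation <- function(sys, L, preincubation_min = 60,
                                 chase_nM = 1000, times, n_rep = 1,
                                 added_cpm = NULL, seed = NULL) {
  stopifnot(is(sys, "SystemParams"))
  .assertScalar(L, "L", positive = TRUE)
  if (chase_nM < 100 * sys@kd_nM)
    stop("chase concentration below 100 x KD: rebinding would not be ",
         "negligible; invalid chase design")
  if (length(times) < 1 || any(diff(times) <= 0) || times[1] < 0)
    stop("times must be ascending and start at >= 0")
  rates <- .kineticRates(sys)
  added <- .addedCpm(sys, added_cpm, L)
  kobs <- rates$kon * L + rates$koff
  beq <- sys@bmax_cpm * L / (L + sys@kd_nM)
  b0 <- beq * (1 - exp(-kobs * preincubation_min))
  .depletionGuard(b0, added)
  spec_mu <- b0 * exp(-rates$koff * times)
  .noisyTrace(sys, times, spec_mu, sys@ns_fraction * added, L,
              "dissociation", n_rep, seed)
}

#' Simulate an equilibrium competition-binding curve
#'
#' Homologous mode (competitor is the unlabelled tracer): expected
#' specific binding is Bmax L / (L + C + KD). Heterologous mode:
#' Bmax L / (L + KD (1 + C/Ki)). The nonspecific channel is the same
#' constant fraction of added counts as in the kinetic simulations and is
#' unaffected by the competitor.
#'
#' @inheritParams simulateAssociation
#' @param competitor_concs competitor concentrations, molar, ascending;
#'   zero is allowed and represents the B0 wells
#' @param ki_nM competitor affinity for heterologous mode, nM
#' @param homologous logical; competitor identical to the tracer?
#' @return a [CompetitionCurve-class]
#' @examples
#' sys <- SystemParams(bmax_cpm = 5e5, kd_nM = 59.3, noise_cv = 0, seed = 1L)
#' cc <- simulateCompetition(sys, L = 0.06,
#'                           competitor_concs = c(0, 10^seq(-10, -5)))
#' @export
simulateCompetition <- function(sys, L, competitor_concs, ki_nM = NA_real_,
                                homologous = TRUE, n_rep = 1,
                                added_cpm = NULL, seed = NULL) {
  stopifnot(is(sys, "SystemParams"))
  .assertScalar(L, "L", positive = TRUE)
  if (any(competitor_concs < 0)) stop("competitor concentrations must be >= 0")
  if (!homologous && (is.na(ki_nM) || ki_nM <= 0))
    stop("heterologous mode requires ki_nM > 0")
  added <- .addedCpm(sys, added_cpm, L)
  c_nM <- competitor_concs * 1e9
  spec_mu <- if (homologous) {
    sys@bmax_cpm * L / (L + c_nM + sys@kd_nM)
  } else {
    sys@bmax_cpm * L / (L + sys@kd_nM * (1 + c_nM / ki_nM))
  }
  .depletionGuard(max(spec_mu), added)
  ns_cpm <- sys@ns_fraction * added
  nc <- length(c_nM)
  .withSeed(if (is.null(seed)) sys@seed else seed, function() {
    bound <- numeric(0); nonspec <- numeric(0); rep_idx <- integer(0)
    for (r in seq_len(n_rep)) {
      bound <- c(bound, .noisyCounts(spec_mu + ns_cpm, sys@noise_cv))
      nonspec <- c(nonspec, .noisyCounts(rep(ns_cpm, nc), sys@noise_cv))
      rep_idx <- c(rep_idx, rep(r, nc))
    }
    CompetitionCurve(competitor_conc = rep(competitor_concs, n_rep),
                     bound = bound, nonspecific = nonspec,
                     tracer_conc_L = L, replicate = rep_idx)
  })
}

#' Simulate a dose-response curve with optional competitive antagonist
#'
#' Expected response is basal + Emax A / (A + EC50 (1 + B/KB)): a
#' logistic with unit Hill slope whose midpoint is right-shifted by the
#' Gaddum factor (1 + B/KB) under a fixed antagonist concentration B.
#'
#' @param fp a [FunctionalParams()] object
#' @param agonist_concs agonist concentrations, molar (0 allowed for
#'   basal wells)
#' @param antagonist_nM fixed antagonist concentration, nM (0 = none;
#'   requires \code{kb_nM} in \code{fp} when positive)
#' @param n_rep number of replicates
#' @param ligand_id,receptor_id labels stamped on the output
#' @param seed optional RNG seed overriding the one in \code{fp}
#' @return a [DoseResponseCurve-class]
#' @examples
#' fp <- FunctionalParams(emax_frac = 1, ec50_nM = 0.16, kb_nM = 51.9,
#'                        noise_cv = 0, seed = 1L)
#' simulateDoseResponse(fp, 10^seq(-12, -7), antagonist_nM = 100)
#' @export
simulateDoseResponse <- function(fp, agonist_concs, antagonist_nM = 0,
                                 n_rep = 1, ligand_id = NA_character_,
                                 receptor_id = NA_character_, seed = NULL) {
  stopifnot(is(fp, "FunctionalParams"))
  if (any(agonist_concs < 0)) stop("agonist concentrations must be >= 0")
  .assertScalar(antagonist_nM, "antagonist_nM", nonneg = TRUE)
  if (antagonist_nM > 0 && is.na(fp@kb_nM))
    stop("antagonist concentration given but kb_nM is not set")
  shift <- if (antagonist_nM > 0) 1 + antagonist_nM / fp@kb_nM else 1
  a_nM <- agonist_concs * 1e9
  mu <- fp@basal + fp@emax_frac * a_nM / (a_nM + fp@ec50_nM * shift)
  nc <- length(a_nM)
  .withSeed(if (is.null(seed)) fp@seed else seed, function() {
    resp <- numeric(0); rep_idx <- integer(0)
    for (r in seq_len(n_rep)) {
      resp <- c(resp, .noisyCounts(mu, fp@noise_cv))
      rep_idx <- c(rep_idx, rep(r, nc))
    }
    DoseResponseCurve(conc = rep(agonist_concs, n_rep), response = resp,
                      replicate = rep_idx, ligand_id = ligand_id,
                      receptor_id = receptor_id)
  })
}

#' Simulate paired BRET acceptor/donor channel readings
#'
#' The expected acceptor/donor ratio follows the logistic of \code{fp};
#' the two channels are noised independently around donor_level and
#' donor_level x ratio.
#'
#' @inheritParams simulateDoseResponse
#' @param concs agonist concentrations, molar
#' @param donor_level expected donor (RLUC) luminescence counts (> 0)
#' @return a data.frame with columns conc_M, acceptor, donor, replicate
#' @export
simulateBret <- function(fp, concs, donor_level, n_rep = 1, seed = NULL) {
  stopifnot(is(fp, "FunctionalParams"))
  .assertScalar(donor_level, "donor_level", positive = TRUE)
  if (any(concs < 0)) stop("concentrations must be >= 0")
  a_nM <- concs * 1e9
  ratio_mu <- fp@basal + fp@emax_frac * a_nM / (a_nM + fp@ec50_nM)
  nc <- length(concs)
  .withSeed(if (is.null(seed)) fp@seed else seed, function() {
    out <- vector("list", n_rep)
    for (r in seq_len(n_rep)) {
      out[[r]] <- data.frame(
        conc_M = concs,
        acceptor = .noisyCounts(donor_level * ratio_mu, fp@noise_cv),
        donor = .noisyCounts(rep(donor_level, nc), fp@noise_cv),
        replicate = r)
    }
    do.call(rbind, out)
  })
}
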