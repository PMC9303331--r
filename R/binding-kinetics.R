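# One-phase binding kinetics.
#
# Under pseudo-first-order conditions specific binding associates as
# plateau (1 - exp(-kobs t)) and dissociates as B0 exp(-koff t). The
# association rate constant follows from kon = (kobs - koff)/[L] and the
# kinetic equilibrium constant from KD = koff/kon; standard errors are
# propagated by the delta method.

.pooledStart <- function(time, spec, phase) {
  top <- max(spec)
  if (phase == "association") {
    idx <- which(spec >= top / 2)
    t_half <- if (length(idx)) max(min(time[idx]), min(time[time > 0])) else
      stats::median(time)
  } else {
    idx <- which(spec <= top / 2)
    t_half <- if (length(idx)) max(min(time[idx]), min(time[time > 0])) else
      stats::median(time)
  }
  k0 <- log(2) / max(t_half, 1e-6)
  list(amplitude = top, rate = min(max(k0, 1e-4), 10))
}

.fitOnePhase <- function(time, spec, phase, free_floor = FALSE) {
  start <- .pooledStart(time, spec, phase)
  df <- data.frame(time = time, spec = spec)
  if (phase == "association") {
    fml <- spec ~ amplitude * (1 - exp(-rate * time))
  } else if (free_floor) {
    fml <- spec ~ floor + amplitude * exp(-rate * time)
  } else {
    fml <- spec ~ amplitude * exp(-rate * time)
  }
  start_list <- list(amplitude = start$amplitude, rate = start$rate)
  lower <- c(amplitude = 0, rate = 1e-8)
  if (phase == "dissociation" && free_floor) {
    start_list$floor <- 0
    lower <- c(lower, floor = 0)
  }
  fit <- minpack.lm::nlsLM(fml, data = df, start = start_list,
                           lower = lower[names(start_list)],
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  ses <- tryCatch(summary(fit)$coefficients[, 2], error = function(e)
    stats::setNames(rep(NA_real_, length(cf)), names(cf)))
  if (cf[["rate"]] <= 1e-8)
    stop("fitted rate is not positive: no ", phase, " signal")
  new("KineticFit", phase = phase, rate = unname(cf[["rate"]]),
      se_rate = unname(ses[["rate"]]), amplitude = unname(cf[["amplitude"]]),
      se_amplitude = unname(ses[["amplitude"]]),
      sse = sum(stats::resid(fit)^2),
      converged = isTRUE(fit$convInfo$isConv),
      n_points = length(spec))
}

#' Fit a one-phase association trace
#'
#' Least-squares fit of specific(t) = plateau (1 - exp(-kobs t)), with
#' B(0) = 0 enforced (the reaction starts when the tracer is added).
#' Replicates are pooled into a single fit.
#'
#' @param trace a [KineticTrace-class] with phase "association" and at
#'   least 10 time points
#' @return a [KineticFit-class]; \code{rateConstant()} is kobs (min^-1)
#'   and \code{amplitude()} the plateau (CPM)
#' @examples
#' sys <- SystemParams(bmax_cpm = 2000, kon = 0.308, koff = 0.010,
#'                     noise_cv = 0, seed = 1L)
#' fit <- fitAssociation(simulateAssociation(sys, L = 0.21, times = 0:100))
#' rateConstant(fit) # kobs = 0.308*0.21 + 0.010 = 0.0747
#' @export
fitAssociation <- function(trace) {
  stopifnot(is(trace, "KineticTrace"))
  if (trace@phase != "association")
    stop("trace phase must be 'association'")
  if (length(trace@time) < 10) stop("need at least 10 time points")
  spec <- trace@specific
  if (max(spec) <= 0 || diff(range(spec)) == 0)
    stop("no association signal: flat trace")
  .fitOnePhase(trace@time, spec, "association")
}

#' Fit a one-phase dissociation trace
#'
#' Least-squares fit of specific(t) = B0 exp(-koff t). The floor is fixed
#' at zero by default (nonspecific binding is already subtracted); set
#' \code{free_floor = TRUE} to fit a nonzero plateau.
#'
#' @param trace a [KineticTrace-class] with phase "dissociation" and at
#'   least 10 time points
#' @param free_floor fit an additive plateau instead of fixing it at 0
#' @return a [KineticFit-class]; \code{rateConstant()} is koff (min^-1)
#'   and \code{amplitude()} the starting level B0 (CPM)
#' @export
fitDissociation <- function(trace, free_floor = FALSE) {
  stopifnot(is(trace, "KineticTrace"))
  if (trace@phase != "dissociation")
    stop("trace phase must be 'dissociation'")
  if (length(trace@time) < 10) stop("need at least 10 time points")
  spec <- trace@specific
  if (stats::coef(stats::lm(spec ~ trace@time))[2] > 0)
    stop("increasing trace: not a dissociation time course")
  .fitOnePhase(trace@time, spec, "dissociation", free_floor = free_floor)
}

#' Association rate constant from kobs, koff and tracer concentration
#'
#' kon = (kobs - koff) / L. kobs must exceed koff (the association
#' component must be present).
#'
#' @param kobs observed association rate, min^-1
#' @param koff dissociation rate constant, min^-1
#' @param L_nM tracer concentration, nM
#' @return kon in nM^-1 min^-1
#' @examples
#' konFromKobs(0.074, 0.010, 0.21) # 0.305
#' @export
konFromKobs <- function(kobs, koff, L_nM) {
  .assertScalar(kobs, "kobs", positive = TRUE)
  .assertScalar(koff, "koff", positive = TRUE)
  .assertScalar(L_nM, "L_nM", positive = TRUE)
  if (kobs <= koff)
    stop("kobs must exceed koff: inconsistent kinetic fits ",
         "(zero association component)")
  (kobs - koff) / L_nM
}

#' Kinetic equilibrium dissociation constant
#'
#' KD = koff / kon, from the rate constants of the one-phase fits.
#'
#' @param koff dissociation rate constant, min^-1
#' @param kon association rate constant, nM^-1 min^-1
#' @return KD in nM
#' @examples
#' kdKinetic(0.010, 0.308) # 0.032
#' @export
kdKinetic <- function(koff, kon) {
  .assertScalar(koff, "koff", positive = TRUE)
  .assertScalar(kon, "kon", positive = TRUE)
  koff / kon
}

#' Derived kinetic constants with delta-method error propagation
#'
#' Combines the association and dissociation fit results into kon and
#' kinetic KD with propagated standard errors:
#' \deqn{SE(kon)^2 = (SE(kobs)^2 + SE(koff)^2)/L^2 +
#'       ((kobs - koff) SE(L) / L^2)^2}
#' \deqn{SE(KD)^2 = (SE(koff)/kon)^2 + (koff SE(kon)/kon^2)^2}
#'
#' @param kobs,se_kobs observed association rate and SE, min^-1
#' @param koff,se_koff dissociation rate constant and SE, min^-1
#' @param L_nM,se_L tracer concentration and SE, nM
#' @param plateau_cpm optional association plateau to carry along
#' @return a [KineticConstants-class]
#' @examples
#' kc <- propagateKineticErrors(0.074, 0.004, 0.010, 0.001, 0.21, 0.004)
#' kOn(kc)   # 0.305 nM^-1 min^-1
#' kdNM(kc)  # 0.0328 nM
#' @export
propagateKineticErrors <- function(kobs, se_kobs, koff, se_koff,
                                   L_nM, se_L = 0, plateau_cpm = NA_real_) {
  for (s in c(se_kobs, se_koff, se_L))
    .assertScalar(s, "standard errors", nonneg = TRUE)
  kon <- konFromKobs(kobs, koff, L_nM)
  se_kon <- sqrt((se_kobs^2 + se_koff^2) / L_nM^2 +
                 ((kobs - koff) * se_L / L_nM^2)^2)
  kd <- kdKinetic(koff, kon)
  se_kd <- sqrt((se_koff / kon)^2 + (koff * se_kon / kon^2)^2)
  new("KineticConstants", kobs = kobs, se_kobs = se_kobs, koff = koff,
      se_koff = se_koff, kon = kon, se_kon = se_kon, kd_nM = kd,
      se_kd = se_kd, tracer_conc_L = L_nM, se_L = se_L,
      plateau_cpm = plateau_cpm)
}

#' End-to-end kinetic analysis of paired association/dissociation traces
#'
#' Fits both traces ([fitAssociation()], [fitDissociation()]) and derives
#' kon and kinetic KD with propagated errors.
#'
#' @param assoc a [KineticTrace-class], phase "association"
#' @param dissoc a [KineticTrace-class], phase "dissociation"
#' @param se_L standard error of the tracer concentration, nM
#' @param free_floor passed to [fitDissociation()]
#' @return a [KineticConstants-class]
#' @export
analyzeKinetics <- function(assoc, dissoc, se_L = 0, free_floor = FALSE) {
  fa <- fitAssociation(assoc)
  fd <- fitDissociation(dissoc, free_floor = free_floor)
  propagateKineticErrors(rateConstant(fa), standardErrors(fa)[["rate"]],
                         rateConstant(fd), standardErrors(fd)[["rate"]],
                         assoc@tracer_conc_L, se_L,
                         plateau_cpm = amplitude(fa))
}
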