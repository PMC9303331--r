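# Independent numeric oracles used to check the generator's closed-form
# expectations and the error propagation.

# One-ligand mass-action ODE: d[RL]/dt = kon L (Bmax - RL) - koff RL,
# with free tracer L held constant (pseudo-first-order).
odeAssociationOracle <- function(bmax, kon, koff, L, times) {
  out <- deSolve::ode(
    y = c(RL = 0), times = times,
    func = function(t, y, p) list(kon * L * (bmax - y[["RL"]]) -
                                    koff * y[["RL"]]))
  unname(out[, "RL"])
}

# Two-ligand oracle for the dissociation chase: tracer (kon, koff) and
# unlabelled competitor (kon_c, koff_c) compete for the same sites; both
# free concentrations held constant. Association for `preinc` minutes,
# then the chase is added and RL is followed over `times`.
odeDissociationOracle <- function(bmax, kon, koff, L, preinc, chase_nM,
                                  times, kon_c = kon, koff_c = koff) {
  rl0 <- odeAssociationOracle(bmax, kon, koff, L, c(0, preinc))[2]
  out <- deSolve::ode(
    y = c(RL = rl0, RC = 0), times = times,
    func = function(t, y, p) {
      free <- bmax - y[["RL"]] - y[["RC"]]
      list(c(kon * L * free - koff * y[["RL"]],
             kon_c * chase_nM * free - koff_c * y[["RC"]]))
    })
  unname(out[, "RL"])
}

# Expected noise-free specific binding of the generator, closed form.
closedFormAssociation <- function(bmax, kon, koff, L, times) {
  kd <- koff / kon
  beq <- bmax * L / (L + kd)
  beq * (1 - exp(-(kon * L + koff) * times))
}

# Extract the noise-free specific channel of a simulated trace.
traceSpecific <- function(trace) trace@specific
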