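test_that("noise-free association round-trip recovers kobs exactly", {
  sys <- SystemParams(bmax_cpm = 2000, kon = 0.308, koff = 0.010,
                      ns_fraction = 0.02, noise_cv = 0)
  tr <- simulateAssociation(sys, L = 0.21, times = 0:100)
  fit <- fitAssociation(tr)
  kobs_true <- 0.308 * 0.21 + 0.010    # 0.0747
  expect_equal(rateConstant(fit), kobs_true, tolerance = 1e-6)
  expect_true(isConverged(fit))
  # time to 95% of plateau is 3/kobs ~ 40 min: equilibrium by ~40 min
  expect_equal(3 / rateConstant(fit), 40.2, tolerance = 0.01)
})

test_that("noise-free dissociation round-trip recovers koff exactly", {
  sys <- SystemParams(bmax_cpm = 2000, kon = 0.115, koff = 0.005,
                      ns_fraction = 0.02, noise_cv = 0)
  tr <- simulateDissociation(sys, L = 0.19, preincubation_min = 60,
                             chase_nM = 1000, times = 0:300)
  fit <- fitDissociation(tr)
  expect_equal(rateConstant(fit), 0.005, tolerance = 1e-6)
  # half of the starting level is reached at ln2/koff
  expect_equal(log(2) / rateConstant(fit), log(2) / 0.005, tolerance = 1e-6)
})

test_that("kinetic fit input guards reject bad traces", {
  sys <- SystemParams(bmax_cpm = 2000, kon = 0.308, koff = 0.010,
                      noise_cv = 0)
  tr <- simulateAssociation(sys, L = 0.21, times = 0:100)
  expect_error(fitDissociation(tr), "phase")
  short <- simulateAssociation(sys, L = 0.21, times = 0:5)
  expect_error(fitAssociation(short), "10 time points")
  flat <- suppressWarnings(
    KineticTrace(time = 0:20, total = rep(100, 21), nonspecific = 100,
                 tracer_conc_L = 0.21, phase = "association"))
  expect_error(fitAssociation(flat), "no association signal")
  rising <- suppressWarnings(
    KineticTrace(time = 0:20, total = 100 + (0:20) * 10, nonspecific = 0,
                 tracer_conc_L = 0.21, phase = "dissociation"))
  expect_error(fitDissociation(rising), "increasing")
})

test_that("kon = (kobs - koff)/L reproduces the reported rate constants", {
  expect_equal(konFromKobs(0.027, 0.005, 0.19), 0.116, tolerance = 5e-3)
  expect_equal(konFromKobs(0.074, 0.010, 0.21), 0.305, tolerance = 1e-3)
  expect_error(konFromKobs(0.010, 0.010, 0.2), "exceed")
  expect_error(konFromKobs(0.005, 0.010, 0.2), "exceed")
})

test_that("kinetic KD = koff/kon", {
  expect_equal(kdKinetic(0.010, 0.308), 0.032, tolerance = 2e-2)
  expect_equal(kdKinetic(0.005, 0.115), 0.0435, tolerance = 1e-3)
  expect_equal(kdKinetic(0.2, 0.2), 1)
  expect_error(kdKinetic(0, 0.1), "koff")
})

test_that("kobs increases with tracer concentration (kobs = kon L + koff)", {
  sys <- SystemParams(bmax_cpm = 2000, kon = 0.2, koff = 0.01,
                      ns_fraction = 0, noise_cv = 0)
  kobs <- vapply(c(0.05, 0.1, 0.2, 0.4), function(L) {
    rateConstant(fitAssociation(simulateAssociation(sys, L, times = 0:120)))
  }, numeric(1))
  expect_true(all(diff(kobs) > 0))
  expect_equal(kobs, 0.2 * c(0.05, 0.1, 0.2, 0.4) + 0.01, tolerance = 1e-4)
})

test_that("delta-method propagation: trivial collapses and internal consistency", {
  kc0 <- propagateKineticErrors(0.074, 0, 0.010, 0, 0.21, 0)
  expect_equal(unname(standardErrors(kc0)), rep(0, 4))
  # SE(L) = SE(koff) = 0 collapses SE(kon) to SE(kobs)/L
  kc1 <- propagateKineticErrors(0.074, 0.004, 0.010, 0, 0.21, 0)
  expect_equal(standardErrors(kc1)[["kon"]], 0.004 / 0.21)
  # stored values are mutually consistent by construction
  kc <- propagateKineticErrors(0.074, 0.004, 0.010, 0.001, 0.21, 0.004)
  expect_equal(kOn(kc), (kObs(kc) - kOff(kc)) / 0.21)
  expect_equal(kdNM(kc), kOff(kc) / kOn(kc))
})

test_that("delta-method SE(kon) matches a Monte-Carlo oracle within 5%", {
  se <- c(kobs = 0.004, koff = 0.001, L = 0.004)
  kc <- propagateKineticErrors(0.074, se[["kobs"]], 0.010, se[["koff"]],
                               0.21, se[["L"]])
  set.seed(11)
  n <- 1e5
  kon_mc <- (rnorm(n, 0.074, se[["kobs"]]) - rnorm(n, 0.010, se[["koff"]])) /
    rnorm(n, 0.21, se[["L"]])
  expect_lt(abs(stats::sd(kon_mc) - standardErrors(kc)[["kon"]]) /
              stats::sd(kon_mc), 0.05)
  kd_mc <- rnorm(n, 0.010, se[["koff"]]) / kon_mc
  expect_lt(abs(stats::sd(kd_mc) - standardErrors(kc)[["kd_nM"]]) /
              stats::sd(kd_mc), 0.10)
})

test_that("kinetic KD of a rate-consistent system equals the equilibrium KD", {
  sys <- SystemParams(bmax_cpm = 2000, kon = 0.25, koff = 0.008,
                      ns_fraction = 0.02, noise_cv = 0)
  assoc <- simulateAssociation(sys, L = 0.2, times = 0:120)
  dissoc <- simulateDissociation(sys, L = 0.2, chase_nM = 1000,
                                 times = 0:400)
  kc <- analyzeKinetics(assoc, dissoc)
  expect_equal(kdNM(kc), kdNM(sys), tolerance = 1e-5)
})

test_that("pooled replicate fitting matches the underlying rates with noise", {
  sys <- SystemParams(bmax_cpm = 2000, kon = 0.308, koff = 0.010,
                      ns_fraction = 0.02, noise_cv = 0.05, seed = 5L)
  assoc <- simulateAssociation(sys, L = 0.21, times = 0:100, n_rep = 4)
  dissoc <- simulateDissociation(sys, L = 0.21, chase_nM = 1000,
                                 times = 0:500, n_rep = 4, seed = 6L)
  kc <- analyzeKinetics(assoc, dissoc)
  expect_lt(abs(kOn(kc) - 0.308) / 0.308, 0.10)
  expect_lt(abs(kOff(kc) - 0.010) / 0.010, 0.10)
  expect_gt(standardErrors(kc)[["kon"]], 0)
})

test_that("free-floor dissociation variant still recovers koff at zero noise", {
  sys <- SystemParams(bmax_cpm = 2000, kon = 0.115, koff = 0.005,
                      ns_fraction = 0.02, noise_cv = 0)
  tr <- simulateDissociation(sys, L = 0.19, chase_nM = 1000, times = 0:400)
  fit <- fitDissociation(tr, free_floor = TRUE)
  expect_equal(rateConstant(fit), 0.005, tolerance = 1e-4)
})
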