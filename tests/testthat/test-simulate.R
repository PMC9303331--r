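test_that("association expectation matches the closed form and an ODE oracle", {
  sys <- SystemParams(bmax_cpm = 1000, kon = 0.1, koff = 0.01,
                      ns_fraction = 0, noise_cv = 0)
  times <- 0:100
  tr <- simulateAssociation(sys, L = 0.2, times = times)
  expect_equal(tr@specific[1], 0)                       # no time to bind
  beq <- 1000 * 0.2 / (0.2 + 0.1)
  expect_equal(tr@specific, beq * (1 - exp(-0.03 * times)))
  ode <- odeAssociationOracle(1000, 0.1, 0.01, 0.2, times)
  rel <- abs(tr@specific[-1] - ode[-1]) / ode[-1]
  expect_lt(max(rel), 1e-3)
})

test_that("per-minute sampling to 100 min gives 101 points per replicate", {
  sys <- SystemParams(bmax_cpm = 1000, kon = 0.308, koff = 0.010,
                      noise_cv = 0.05, seed = 7L)
  tr <- simulateAssociation(sys, L = 0.21, times = 0:100, n_rep = 3)
  expect_equal(sum(tr@replicate == 1L), 101L)
  expect_equal(length(tr@time), 3 * 101L)
})

test_that("fixed seed reproduces bit-for-bit; seed changes noise only", {
  sys <- SystemParams(bmax_cpm = 1000, kon = 0.1, koff = 0.01,
                      noise_cv = 0.1, seed = 42L)
  a <- simulateAssociation(sys, L = 0.2, times = 0:30, n_rep = 2)
  b <- simulateAssociation(sys, L = 0.2, times = 0:30, n_rep = 2)
  expect_identical(a@total, b@total)
  expect_identical(a@nonspecific, b@nonspecific)
  c <- simulateAssociation(sys, L = 0.2, times = 0:30, n_rep = 2, seed = 43L)
  expect_false(identical(a@total, c@total))
  # expectations are seed-independent
  sys0 <- SystemParams(bmax_cpm = 1000, kon = 0.1, koff = 0.01,
                       noise_cv = 0, seed = 42L)
  d <- simulateAssociation(sys0, L = 0.2, times = 0:30)
  e <- simulateAssociation(sys0, L = 0.2, times = 0:30, seed = 43L)
  expect_identical(d@specific, e@specific)
})

test_that("dissociation decays exponentially and matches the two-ligand ODE oracle", {
  sys <- SystemParams(bmax_cpm = 1000, kon = 0.1, koff = 0.01,
                      ns_fraction = 0, noise_cv = 0)
  times <- 0:300
  tr <- simulateDissociation(sys, L = 0.2, preincubation_min = 60,
                             chase_nM = 1000, times = times)
  b0 <- tr@specific[1]
  expect_equal(b0, closedFormAssociation(1000, 0.1, 0.01, 0.2, 60))
  expect_true(all(diff(tr@specific) <= 0))              # non-increasing
  # half-life ln2/koff
  t_half <- log(2) / 0.01
  expect_equal(stats::approx(times, tr@specific, xout = t_half)$y, b0 / 2,
               tolerance = 1e-3)
  # the two-ligand oracle includes the brief rebinding window before the
  # chase saturates the free receptors; the closed form stays within 1%
  # pointwise and the oracle's half-life matches ln2/koff to 0.1%
  ode <- odeDissociationOracle(1000, 0.1, 0.01, 0.2, preinc = 60,
                               chase_nM = 1000, times = times)
  rel <- abs(tr@specific - ode) / pmax(ode, 1e-9)
  expect_lt(max(rel), 0.01)
  t_half_ode <- stats::approx(ode, times, xout = ode[1] / 2)$y
  expect_equal(t_half_ode, log(2) / 0.01, tolerance = 1e-3)
})

test_that("a chase below 100 x KD is rejected as invalid design", {
  sys <- SystemParams(bmax_cpm = 1000, kon = 0.1, koff = 0.01) # KD 0.1 nM
  expect_error(simulateDissociation(sys, L = 0.2, chase_nM = 5, times = 0:60),
               "chase")
  # the assay's 1 uM chase vs sub-nM KD passes easily
  sys2 <- SystemParams(bmax_cpm = 1000, kon = 0.308, koff = 0.010)
  expect_s4_class(simulateDissociation(sys2, L = 0.21, chase_nM = 1000,
                                       times = 0:60, seed = 1L),
                  "KineticTrace")
})

test_that("tracer-depletion guard warns when bound exceeds 10% of added", {
  sys <- SystemParams(bmax_cpm = 1000, kon = 0.1, koff = 0.001,
                      ns_fraction = 0, noise_cv = 0)  # KD 0.01: near-total occupancy
  expect_warning(simulateAssociation(sys, L = 0.2, times = 0:10,
                                     added_cpm = 2000),
                 "pseudo-first-order")
  expect_silent(simulateAssociation(sys, L = 0.2, times = 0:10,
                                    added_cpm = 1e5))
})

test_that("competition expectations: B0 well, full displacement, plateau consistency", {
  sys <- SystemParams(bmax_cpm = 5000, kon = 0.1, koff = 0.01,
                      ns_fraction = 0.02, noise_cv = 0)
  L <- 0.2
  cc <- simulateCompetition(sys, L = L, competitor_concs = c(0, 1e-9, 1e-3))
  spec <- specificBinding(cc@bound, cc@nonspecific)
  # C = 0: specific = Bmax L/(L + KD)
  expect_equal(spec[1], 5000 * L / (L + 0.1))
  # C -> infinity: specific -> 0, nonspecific untouched
  expect_lt(spec[3], 1e-3 * spec[1])
  expect_equal(cc@nonspecific[3], cc@nonspecific[1])
  # equilibrium generator agrees with the kinetic plateau for the same L
  tr <- simulateAssociation(sys, L = L, times = c(0, 5000))
  expect_equal(spec[1], tr@specific[2], tolerance = 1e-9)
})

test_that("homologous IC50 equals L + KD (root-finding oracle on the closed form)", {
  bmax <- 5000; kd <- 40; L <- 0.05
  f <- function(C_nM) bmax * L / (L + C_nM + kd) - 0.5 * bmax * L / (L + kd)
  ic50 <- stats::uniroot(f, c(1e-6, 1e6), tol = 1e-10)$root
  expect_equal(ic50, L + kd, tolerance = 1e-6)
  # and the generator reproduces that expectation
  sys <- SystemParams(bmax_cpm = bmax, kd_nM = kd, ns_fraction = 0,
                      noise_cv = 0)
  cc <- simulateCompetition(sys, L = L, competitor_concs = ic50 * 1e-9)
  expect_equal(cc@bound[1], 0.5 * bmax * L / (L + kd), tolerance = 1e-9)
})

test_that("heterologous mode requires a positive Ki", {
  sys <- SystemParams(bmax_cpm = 5000, kd_nM = 40, noise_cv = 0)
  expect_error(simulateCompetition(sys, L = 0.05, competitor_concs = 1e-8,
                                   homologous = FALSE),
               "ki_nM")
})

test_that("dose-response generator: half-max at EC50 and Gaddum shift", {
  fp <- FunctionalParams(basal = 0.05, emax_frac = 0.9, ec50_nM = 5,
                         kb_nM = 50, noise_cv = 0)
  dr <- simulateDoseResponse(fp, agonist_concs = 5e-9)
  expect_equal(dr@response, 0.05 + 0.9 / 2)
  # antagonist at B = KB doubles the apparent EC50: response at EC50 drops
  dr2 <- simulateDoseResponse(fp, agonist_concs = 5e-9, antagonist_nM = 50)
  expect_equal(dr2@response, 0.05 + 0.9 * 5 / (5 + 10))
  expect_error(simulateDoseResponse(
    FunctionalParams(emax_frac = 1, ec50_nM = 5, noise_cv = 0),
    agonist_concs = 5e-9, antagonist_nM = 50), "kb_nM")
})

test_that("partial-agonist profile: emax_frac 0.11 caps the curve at 11%", {
  fp <- FunctionalParams(basal = 0, emax_frac = 0.11, ec50_nM = 27.5,
                         noise_cv = 0)
  dr <- simulateDoseResponse(fp, agonist_concs = 1e-4)  # saturating
  expect_equal(100 * dr@response, 11, tolerance = 1e-2)
})

test_that("BRET generator: constant ratio at zero efficacy, half-max at EC50", {
  fp0 <- FunctionalParams(basal = 0.1, emax_frac = 0, ec50_nM = 5,
                          noise_cv = 0)
  b0 <- simulateBret(fp0, concs = 10^seq(-10, -6), donor_level = 1e5)
  expect_equal(bretRatio(b0$acceptor, b0$donor), rep(0.1, 5))
  fp <- FunctionalParams(basal = 0.1, emax_frac = 0.4, ec50_nM = 5,
                         noise_cv = 0)
  b1 <- simulateBret(fp, concs = 5e-9, donor_level = 1e5)
  expect_equal(bretRatio(b1$acceptor, b1$donor), 0.1 + 0.4 / 2)
})

test_that("noise-free BRET ratio curve refit recovers the true pEC50", {
  true_pec50 <- 8.5
  fp <- FunctionalParams(basal = 0.05, emax_frac = 0.5,
                         ec50_nM = 10^(9 - true_pec50), noise_cv = 0)
  b <- simulateBret(fp, concs = 10^seq(-11, -6, 0.5), donor_level = 1e5)
  curve <- DoseResponseCurve(conc = b$conc_M,
                             response = bretRatio(b$acceptor, b$donor))
  fit <- fitLogistic(curve, mode = "activation")
  expect_equal(pEC50(fit), true_pec50, tolerance = 0.02 / true_pec50)
})

test_that("SystemParams enforces its invariants", {
  expect_error(SystemParams(bmax_cpm = -1, kd_nM = 1), "bmax")
  expect_error(SystemParams(bmax_cpm = 100, kon = 0.1, koff = 0.01,
                            kd_nM = 0.5), "inconsistent")
  expect_error(SystemParams(bmax_cpm = 100, kd_nM = 1, ns_fraction = 1),
               "ns_fraction")
  sys <- SystemParams(bmax_cpm = 100, kon = 0.308, koff = 0.010)
  expect_equal(kdNM(sys), 0.010 / 0.308)
  expect_error(simulateAssociation(SystemParams(bmax_cpm = 100, kd_nM = 1),
                                   L = 0.2, times = 0:10), "kon and koff")
  expect_error(simulateAssociation(sys, L = 0.2, times = c(5, 3, 1)),
               "ascending")
  expect_error(simulateAssociation(sys, L = -1, times = 0:10), "L")
})
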