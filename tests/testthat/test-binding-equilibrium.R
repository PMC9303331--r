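test_that("specific binding subtracts background and clamps noise below it", {
  expect_equal(specificBinding(1000, 200), 800)
  expect_equal(specificBinding(200, 200), 0)
  expect_warning(out <- specificBinding(c(150, 500), c(200, 200)),
                 "NEG_SPECIFIC_CLAMPED")
  expect_equal(out, c(0, 300))
  expect_error(specificBinding(1:3, 1:2), "equal length")
})

test_that("homologous Eq. arithmetic: Bmax = B0 IC50/L and KD = IC50 - L", {
  expect_equal(bmaxHomologous(1000, 60, 0.06), 1e6)
  expect_equal(bmaxHomologous(1000, 0.06, 0.06), 1000)   # ic50 = L forces b0
  expect_equal(kdHomologous(59.36, 0.06), 59.3)
  expect_equal(kdHomologous(0.06, 0.06), 0)
  expect_equal(kdHomologous(10, 1e-12), 10, tolerance = 1e-9) # L -> 0 limit
  expect_error(kdHomologous(0.05, 0.06), "inconsistency")
  expect_error(bmaxHomologous(1000, 60, -1), "L_nM")
})

test_that("Cheng-Prusoff: limits at L = 0 and L = KD, monotone in L", {
  expect_equal(kiChengPrusoff(126, 0, 59.3), 126)
  expect_equal(kiChengPrusoff(126, 59.3, 59.3), 63)
  expect_equal(kiChengPrusoff(126, 0.06, 59.3), 126 / (1 + 0.06 / 59.3))
  expect_equal(kiChengPrusoff(126, 0.06, 59.3), 125.9, tolerance = 1e-3)
  ki <- vapply(c(0, 1, 10, 100), kiChengPrusoff, numeric(1),
               ic50_nM = 126, kd_nM = 59.3)
  expect_true(all(diff(ki) < 0))
  expect_error(kiChengPrusoff(126, 0.06, 0), "kd_nM")
})

test_that("noise-free homologous fit recovers IC50 = L + KD, KD and Bmax", {
  bmax <- 5e5; kd <- 40; L <- 0.05
  sys <- SystemParams(bmax_cpm = bmax, kd_nM = kd, ns_fraction = 0.02,
                      noise_cv = 0)
  cc <- simulateCompetition(sys, L = L,
                            competitor_concs = c(0, 10^seq(-10, -4, 0.5)))
  res <- analyzeCompetition(cc, "homologous")
  expect_equal(ic50nM(res), L + kd, tolerance = 1e-3)
  expect_equal(kdNM(res), kd, tolerance = 1e-3)
  expect_equal(bmaxCpm(res), bmax, tolerance = 1e-3)
  expect_true(is.na(kiNM(res)))
})

test_that("homologous consistency holds across a (KD, L) grid at zero noise", {
  for (kd in c(5, 40, 60)) {
    for (L in c(0.013, 0.05, 0.086)) {     # tracer range of the assay, nM
      sys <- SystemParams(bmax_cpm = 2e5, kd_nM = kd, ns_fraction = 0.01,
                          noise_cv = 0)
      cc <- simulateCompetition(sys, L = L,
                                competitor_concs = c(0, 10^seq(-11, -4, 0.5)))
      res <- analyzeCompetition(cc, "homologous")
      expect_lt(abs(kdNM(res) - kd) / kd, 0.01)
      expect_lt(abs(bmaxCpm(res) - 2e5) / 2e5, 0.01)
    }
  }
})

test_that("Cheng-Prusoff reduces to the homologous identity when Ki = KD", {
  bmax <- 2e5; kd <- 40; L <- 0.05
  sys <- SystemParams(bmax_cpm = bmax, kd_nM = kd, ns_fraction = 0,
                      noise_cv = 0)
  cc <- simulateCompetition(sys, L = L, ki_nM = kd, homologous = FALSE,
                            competitor_concs = c(0, 10^seq(-10, -4, 0.5)))
  res <- analyzeCompetition(cc, "heterologous", tracer_kd_nM = kd)
  expect_equal(kiNM(res), kd, tolerance = 1e-3 * kd)
  expect_true(is.na(kdNM(res)))
})

test_that("heterologous fit recovers the competitor Ki at zero noise", {
  sys <- SystemParams(bmax_cpm = 2e5, kd_nM = 59.3, ns_fraction = 0.02,
                      noise_cv = 0)
  ki_true <- 130
  cc <- simulateCompetition(sys, L = 0.06, ki_nM = ki_true,
                            homologous = FALSE,
                            competitor_concs = c(0, 10^seq(-10, -3, 0.5)))
  res <- analyzeCompetition(cc, "heterologous", tracer_kd_nM = 59.3)
  expect_equal(kiNM(res), ki_true, tolerance = 0.01 * ki_true)
})

test_that("flat displacement curves are reported as N.B. with no numeric IC50", {
  set.seed(2)
  concs <- c(0, 10^seq(-10, -5, 0.5))
  cc <- CompetitionCurve(competitor_conc = concs,
                         bound = rnorm(length(concs), 500, 10),
                         tracer_conc_L = 0.05)
  res <- analyzeCompetition(cc, "homologous")
  expect_true(res@nb)
  expect_true(is.na(ic50nM(res)))
  rep <- reportBinding(list(x = res), n = 3)
  expect_equal(rep$constant_nM, "N.B.")
})

test_that("fitCompetition enforces design preconditions", {
  cc <- CompetitionCurve(competitor_conc = c(0, 1e-9, 2e-9, 3e-9, 4e-9),
                         bound = c(100, 90, 80, 70, 60),
                         tracer_conc_L = 0.05)
  expect_error(fitCompetition(cc), "2 log units")
})

test_that("pIC50/IC50 conversion follows 10^(9 - pIC50)", {
  # a fitted pIC50 of 7.4 corresponds to ~39.8 nM
  expect_equal(10^(9 - 7.4), 39.8, tolerance = 1e-3)
  sys <- SystemParams(bmax_cpm = 1e5, kd_nM = 10^(9 - 7.4) - 0.05,
                      ns_fraction = 0, noise_cv = 0)
  cc <- simulateCompetition(sys, L = 0.05,
                            competitor_concs = c(0, 10^seq(-10, -4, 0.5)))
  res <- analyzeCompetition(cc, "homologous")
  expect_equal(pIC50(res), 7.4, tolerance = 1e-4)
})

test_that("Bmax CPM-to-density conversion round-trips the simulator truth", {
  bmax <- 3e5; sa <- 3.1; cells <- 1.5e5   # CPM/fmol, cells per well
  sys <- SystemParams(bmax_cpm = bmax, kd_nM = 40, ns_fraction = 0.02,
                      noise_cv = 0)
  cc <- simulateCompetition(sys, L = 0.05,
                            competitor_concs = c(0, 10^seq(-10, -4, 0.5)))
  res <- analyzeCompetition(cc, "homologous")
  est <- bmaxToFmolPer1e5Cells(bmaxCpm(res), sa, cells)
  truth <- bmax / sa / (cells / 1e5)
  expect_lt(abs(est - truth) / truth, 0.01)
})
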