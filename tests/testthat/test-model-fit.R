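# Three-pool model fitting: priors, parameter recovery, CESTR*.

test_that("default priors encode the three-pool setup", {
  pr <- defaultPriors()
  expect_equal(pr@poolPriors$offset, c(2.8, -3.5))
  expect_equal(pr@waterT1Mean, 1.8)
  expect_equal(pr@waterT2Mean, 0.1)
  expect_gt(min(pr@poolPriors$logRateSd), 0)
})

test_that("measured priors replace only the water relaxation means", {
  pr <- measuredPriors(1.2, 0.06)
  d <- defaultPriors()
  expect_equal(pr@waterT1Mean, 1.2)
  expect_equal(pr@waterT2Mean, 0.06)
  expect_equal(pr@waterT1Sd, d@waterT1Sd)
  expect_equal(pr@poolPriors, d@poolPriors)
  expect_equal(measuredPriors(1.8, 0.1), d)
  expect_error(measuredPriors(-1, 0.1), "positive")
})

test_that("noise-free self-generated spectra are recovered (inverse crime)", {
  sch <- saturationScheme()
  for (ph in c(6.3, 7.0)) {
    sys <- phantomSystem(ph, 8, 1.7, 0.14, "tumour")
    s <- simulateZSpectrum(sys, sch)
    fit <- fitZSpectrum(s, sch, measuredPriors(1.7, 0.14))
    gt <- phToRate(ph, "amine", "tumour") * bsaToFraction(8, "amine")
    expect_true(fit@converged)
    expect_gt(fit@r2, 0.999)
    expect_lt(abs(fit@kfProduct / gt - 1), 0.05)
    expect_lt(abs(fit@estimates[["t1_water"]] - 1.7), 0.1)
  }
})

test_that("a zero-fraction pool is recovered as consistent with zero", {
  sch <- saturationScheme()
  null3 <- spinSystem(waterPool(1.7, 0.14),
                      exchangePool("amine", 2.8, 1000, 0, 1, 0.01),
                      exchangePool("noe", -3.5, 20, 2e-3, 1, 0.005))
  s <- simulateZSpectrum(null3, sch)
  fit <- fitZSpectrum(s, sch, measuredPriors(1.7, 0.14))
  # kf posterior either tiny or dominated by its uncertainty
  expect_true(fit@kfProduct < 0.05 || fit@kfLogSd > 0.5)
})

test_that("fitted B0 shift tracks an injected frequency offset", {
  sch <- saturationScheme()
  sysOff <- spinSystem(waterPool(1.7, 0.14),
                       exchangePool("amine", 2.9, 2000, 1.5e-3, 1, 0.01),
                       exchangePool("noe", -3.4, 20, 2e-3, 1, 0.005))
  sysOff@pools[[1]]@offset <- 0.1  # the whole system sits 0.1 ppm off
  s <- simulateZSpectrum(sysOff, sch)
  fit <- fitZSpectrum(s, sch, measuredPriors(1.7, 0.14))
  expect_lt(abs(fit@estimates[["b0"]] - 0.1), 0.01)
})

test_that("rate and fraction posteriors are correlated; product reported", {
  sch <- saturationScheme()
  sys <- phantomSystem(7.4, 8, 1.7, 0.14, "tumour")
  s <- simulateZSpectrum(sys, sch)
  fit <- fitZSpectrum(s, sch, measuredPriors(1.7, 0.14))
  V <- fit@details$cov
  corKF <- V[1, 2] / sqrt(V[1, 1] * V[2, 2])
  # the spectrum constrains the rate-fraction pair jointly, never each
  # alone, so the posterior is correlated and downstream analysis uses
  # the product with its covariance-aware uncertainty
  expect_gt(abs(corKF), 0.2)
  expect_gt(fit@kfProduct, 0)
  expect_true(is.finite(fit@kfLogSd) && fit@kfLogSd >= 0)
})

test_that("CESTR* reproduces the generating two-pool signal difference", {
  sch <- saturationScheme()
  k <- 1500; f <- 1.5e-3
  sys2 <- spinSystem(waterPool(1.8, 0.1),
                     exchangePool("amine", 2.8, k, f, 1.0, 0.01))
  s <- simulateZSpectrum(sys2, sch)
  fit <- fitZSpectrum(s, sch)  # default priors centred at this truth
  cs <- cestrStar(fit, sch)
  # truth: water-only minus two-pool signal at 2.8 ppm, same relaxation
  w <- simulateZSpectrum(spinSystem(waterPool(1.8, 0.1)),
                         saturationScheme(offsets = 2.8))
  s2 <- simulateZSpectrum(sys2, saturationScheme(offsets = 2.8))
  truth <- 100 * (normalizedSignals(w) - normalizedSignals(s2))
  expect_lt(abs(cs$value / truth - 1), 0.05)
  expect_gte(cs$sd, 0)
})

test_that("CESTR* is zero for a zero fitted fraction and guards errors", {
  fit <- new("CESTFit",
             estimates = c(rate_amine = 1000, fraction_amine = 0,
                           rate_noe = 20, fraction_noe = 1e-3,
                           t1_water = 1.8, t2_water = 0.1, b0 = 0),
             se = numeric(7), kfProduct = 0, kfLogSd = 0, r2 = 0.999,
             converged = TRUE, nStarts = 1,
             details = list(cestPool = "amine"))
  cs <- cestrStar(fit, saturationScheme())
  expect_identical(cs$value, 0)
  fit@converged <- FALSE
  expect_error(cestrStar(fit, saturationScheme()), "converged")
})

test_that("CESTR* depends on the assumed relaxation constants", {
  # same exchange parameters evaluated under default vs phantom-specific
  # relaxation: quantifies the prior dependence of the metric
  sch <- saturationScheme()
  sys <- phantomSystem(6.64, 8, 0.3, 0.14, "tumour")
  s <- simulateZSpectrum(sys, sch)
  fit <- fitZSpectrum(s, sch, measuredPriors(0.3, 0.14))
  csDefault <- cestrStar(fit, sch, priors = defaultPriors())
  csTrue <- cestrStar(fit, sch, priors = measuredPriors(0.3, 0.14))
  expect_gt(abs(csDefault$value - csTrue$value),
            0.1 * abs(csDefault$value))
})

test_that("the MCMC audit backend agrees with the Laplace approximation", {
  sch <- saturationScheme(nPulses = 60)
  sys <- phantomSystem(6.64, 8, 1.7, 0.14, "tumour")
  set.seed(77)
  raw <- simulateZSpectrum(sys, sch)
  s <- zSpectrum(offsets(raw), signals(raw) + rnorm(85, 0, 0.003),
                 z0 = z0(raw))
  fit <- fitZSpectrum(s, sch, measuredPriors(1.7, 0.14), method = "mcmc",
                      mcmcIter = 600)
  mc <- fit@details$mcmc
  expect_gt(mc$acceptance, 0.05)
  lkf <- log10(fit@kfProduct)
  mcKf <- mc$mean[["lk_amine"]] + mc$mean[["lf_amine"]]
  expect_lt(abs(mcKf - lkf), 0.2)
})
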