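# Statistical engine: regressions, Holm-Sidak correction, ideal-metric
# model, quadrature significance and pH back-calculation.

test_that("metric regression handles exact, null and degenerate cases", {
  x <- 1:6
  r <- regressMetric(2 * x, x)
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_lt(r$p, 1e-10)
  rc <- regressMetric(rep(3, 6), x)
  expect_identical(rc$slope, 0)
  expect_identical(rc$p, 1)
  expect_error(regressMetric(1:5, rep(2, 5)), "degenerate")
  expect_error(regressMetric(1:2, 1:2), "3 phantoms")
})

test_that("Sidak per-rank thresholds match the closed form", {
  th16 <- holmSidakThresholds(16)
  expect_equal(th16[1], 1 - 0.95^(1 / 16), tolerance = 1e-12)
  # effective single-test levels of roughly 0.003, as quoted for families
  # of this size
  expect_equal(th16[1], 0.0032, tolerance = 1e-3)
  expect_equal(holmSidakThresholds(24)[1], 0.00213, tolerance = 1e-2)
  expect_equal(holmSidakThresholds(1), 0.05, tolerance = 1e-12)
  for (m in c(6, 16, 24))
    expect_equal(holmSidakThresholds(m),
                 1 - (1 - 0.05)^(1 / (m - seq_len(m) + 1)), tolerance = 1e-12)
})

test_that("Holm-Sidak decisions match brute-force step-down enumeration", {
  stepDownReject <- function(p, alpha = 0.05) {
    # direct enumeration: walk ranks in order, stop at first acceptance
    m <- length(p)
    ord <- order(p)
    rej <- logical(m)
    for (i in seq_len(m)) {
      if (p[ord[i]] <= 1 - (1 - alpha)^(1 / (m - i + 1))) rej[ord[i]] <- TRUE
      else break
    }
    rej
  }
  set.seed(91)
  for (rep in 1:50) {
    m <- sample(2:24, 1)
    p <- runif(m)^sample(1:3, 1)
    adj <- holmSidakAdjust(p)
    expect_equal(adj <= 0.05, stepDownReject(p))
    # adjusted p-values are monotone in the raw p-values
    expect_true(all(diff(adj[order(p)]) >= -1e-14))
    # never rejects where unadjusted 0.05 would not
    expect_true(all(p[adj <= 0.05] <= 0.05))
  }
})

test_that("slope comparison is null for identical regressions", {
  a <- regressMetric(c(1.1, 2.0, 2.9, 4.2, 5.1), 1:5)
  cs <- compareSlopes(a, a, familySize = 24)
  expect_equal(cs$t, 0)
  expect_equal(cs$p, 1)
  expect_error(compareSlopes(a, a, familySize = 0), "familySize")
})

test_that("ideal-metric model recovers exact coefficients and r2", {
  d <- buildDesign()
  v <- 2 * d$ph + 0.5 * d$bsa - 10
  f <- fitIdealModel(v, d$ph, d$bsa)
  expect_equal(f$alpha, 2, tolerance = 1e-10)
  expect_equal(f$beta, 0.5, tolerance = 1e-10)
  expect_equal(f$epsilon, -10, tolerance = 1e-9)
  expect_equal(f$r2, 1, tolerance = 1e-12)

  # metric driven only by T1 has no specificity
  v2 <- 3 * d$t1 + rnorm(nrow(d), 0, 1e-3)
  f2 <- fitIdealModel(v2, d$ph, d$bsa)
  expect_lt(f2$r2, 0.2)

  # scale equivariance
  f3 <- fitIdealModel(10 * v, d$ph, d$bsa)
  expect_equal(c(f3$alpha, f3$beta, f3$epsilon),
               10 * c(f$alpha, f$beta, f$epsilon), tolerance = 1e-8)
  expect_equal(f3$r2, f$r2, tolerance = 1e-12)

  expect_error(fitIdealModel(v[d$varied_parameter == "t1"],
                             d$ph[d$varied_parameter == "t1"],
                             d$bsa[d$varied_parameter == "t1"]),
               "rank-deficient")
})

test_that("quadrature significance rule matches hand-computed cases", {
  r <- deltaCestSignificance(list(value = 2, sd = 0.3),
                             list(value = 1, sd = 0.4))
  expect_equal(r$delta, 1)
  expect_equal(r$sigma, 0.5)
  expect_true(r$significant)
  r2 <- deltaCestSignificance(list(value = 2, sd = 1),
                              list(value = 1.5, sd = 1))
  expect_equal(r2$sigma, sqrt(2))
  expect_false(r2$significant)
  r3 <- deltaCestSignificance(list(value = 2, sd = 0.1),
                              list(value = 2, sd = 0.1))
  expect_false(r3$significant)
})

test_that("pH back-calculation inverts the forward model exactly", {
  model <- list(alpha = -1.7, beta = 0.42)
  expect_equal(deltaPH(model$alpha, 0, model), 1)
  expect_equal(deltaPH(model$beta * 3, 3, model), 0)
  set.seed(17)
  for (i in 1:25) {
    dph <- runif(1, -1.5, 1.5)
    dbsa <- runif(1, -8, 8)
    dcest <- model$alpha * dph + model$beta * dbsa
    expect_equal(deltaPH(dcest, dbsa, model), dph, tolerance = 1e-10)
  }
  expect_error(deltaPH(1, 0, list(alpha = 0, beta = 1)), "alpha")
})

test_that("sign accuracy groups behave at the extremes", {
  mk <- function(calcSign) {
    exp <- c(-1.2, -0.8, -0.3, 0.2, 0.4, 0.9, 1.1)
    data.frame(significant = TRUE, calculatedDeltaPH = calcSign * exp,
               experimentalDeltaPH = exp,
               signCorrect = sign(calcSign * exp) == sign(exp))
  }
  perfect <- signAccuracy(mk(1))
  expect_equal(perfect$accuracy, c(100, 100, 100))
  inverted <- signAccuracy(mk(-1))
  expect_equal(inverted$accuracy[inverted$group %in% c("below", "above")],
               c(0, 0))
  # empty groups are undefined, not zero
  one <- data.frame(significant = TRUE, calculatedDeltaPH = 1,
                    experimentalDeltaPH = 0.1, signCorrect = TRUE)
  sa <- signAccuracy(one)
  expect_true(is.na(sa$accuracy[sa$group == "below"]))
  expect_equal(sa$nSignificant[sa$group == "middle"], 1)
})

test_that("pairwise table obeys the significance gate", {
  tab <- data.frame(id = c("a", "b", "c"), ph = c(6.0, 7.0, 7.4),
                    bsa = c(8, 8, 8), value = c(5, 2, 1.9),
                    sd = c(0.2, 0.2, 0.2))
  model <- list(alpha = -2.1, beta = 0.4)
  pr <- deltaPHPairs(tab, model)
  expect_equal(nrow(pr), 3)
  ab <- pr[pr$id1 == "a" & pr$id2 == "b", ]
  expect_true(ab$significant)
  expect_equal(ab$deltaCest, 3)
  expect_equal(ab$calculatedDeltaPH, 3 / -2.1, tolerance = 1e-12)
  expect_true(ab$signCorrect)  # negative calculated, negative experimental
  bc <- pr[pr$id1 == "b" & pr$id2 == "c", ]
  expect_false(bc$significant)
  expect_true(is.na(bc$calculatedDeltaPH))
})
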