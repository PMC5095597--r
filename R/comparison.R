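# Statistical engine: per-parameter linear regressions, cross-model slope
# comparison with Holm-Sidak correction, the ideal-metric linear model with
# its specificity R-squared, and pH-difference quantification.

#' Linear regression of a metric against a varied parameter
#'
#' Ordinary least squares of metric value on the serially varied parameter,
#' with the two-sided p-value for slope != 0.
#'
#' @param values metric values (one per phantom in the arm).
#' @param parameterValues the varied parameter's values.
#' @return list: `slope`, `se`, `p`, `intercept`, `n`, `df`.
#' @export
regressMetric <- function(values, parameterValues) {
  if (length(values) < 3L) stop("need at least 3 phantoms")
  if (length(values) != length(parameterValues))
    stop("length mismatch")
  if (var(parameterValues) == 0)
    stop("degenerate design: parameter values all equal")
  if (var(values) == 0) {
    # a constant response carries no evidence of dependence; the t statistic
    # is 0/0 there, so report the no-effect limit directly
    return(list(slope = 0, se = 0, p = 1, intercept = values[1],
                n = length(values), df = length(values) - 2L))
  }
  fit <- lm(values ~ parameterValues)
  sm <- suppressWarnings(summary(fit))$coefficients
  list(slope = sm[2, 1], se = sm[2, 2], p = sm[2, 4],
       intercept = sm[1, 1], n = length(values), df = fit$df.residual)
}

#' Sidak per-rank thresholds for Holm-Sidak step-down
#'
#' Rank i (of m ordered p-values) is tested at `1 - (1 - alpha)^(1/(m-i+1))`.
#'
#' @param m family size.
#' @param alpha family-wise error rate.
#' @return vector of per-rank thresholds (rank 1 first).
#' @export
holmSidakThresholds <- function(m, alpha = 0.05) {
  if (m < 1) stop("family size must be >= 1")
  1 - (1 - alpha)^(1 / (m - seq_len(m) + 1))
}

#' Holm-Sidak step-down adjusted p-values
#'
#' Step-down Sidak: order the raw p-values, adjust rank i as
#' `1 - (1 - p_(i))^(m-i+1)`, enforce monotonicity, and return in the
#' original order. Rejections at level alpha match testing each rank against
#' [holmSidakThresholds()] with step-down stopping.
#'
#' @param p raw p-values.
#' @param m family size (defaults to `length(p)`; may be larger when the
#'   declared family includes tests not in `p`).
#' @return adjusted p-values in the input order.
#' @export
holmSidakAdjust <- function(p, m = length(p)) {
  if (m < length(p)) stop("family size smaller than number of p-values")
  ord <- order(p)
  adj <- 1 - (1 - p[ord])^(m - seq_along(p) + 1)
  adj <- cummax(pmin(adj, 1))
  out <- numeric(length(p))
  out[ord] <- adj
  out
}

#' Compare regression slopes between phantom models
#'
#' Welch-type t-test on the absolute slope values using the regression
#' standard errors, with Satterthwaite degrees of freedom from the two
#' regressions' residual dfs. Intended to be corrected over the declared
#' family with [holmSidakAdjust()].
#'
#' @param a,b [regressMetric()] results for the same metric and parameter in
#'   the two phantom models.
#' @param familySize declared family size for the Holm-Sidak correction.
#' @return list: `t`, `df`, `p` (raw), `pAdjustedBound` (Sidak-adjusted at
#'   the smallest rank, a lower bound on the step-down adjusted p).
#' @export
compareSlopes <- function(a, b, familySize = 24) {
  if (familySize < 1) stop("familySize must be >= 1")
  seSum <- sqrt(a$se^2 + b$se^2)
  t <- (abs(a$slope) - abs(b$slope)) / seSum
  df <- seSum^4 / (a$se^4 / a$df + b$se^4 / b$df)
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p,
       pAdjustedBound = 1 - (1 - p)^familySize)
}

#' Fit the ideal-metric linear model and specificity R-squared
#'
#' Pools the metric values over both phantom models and fits
#' `effect = alpha * pH + beta * BSA + epsilon` by least squares. Theoretical
#' effects are then computed for every phantom (including the relaxation
#' arms, where pH and BSA sit at baseline) and the squared Pearson
#' correlation between theoretical and measured effects is the specificity
#' R-squared: a metric contaminated by T1/T2 varies where the ideal model
#' predicts a constant, lowering R-squared.
#'
#' @param values measured metric values, one per phantom (%M0).
#' @param ph,bsa per-phantom pH and BSA values.
#' @return list: `alpha` (%M0/pH), `beta` (%M0/%BSA), `epsilon` (%M0),
#'   `theoretical`, `r2`, `degenerate` (TRUE when the theoretical effects
#'   have no variance and R-squared is clipped to 0).
#' @export
fitIdealModel <- function(values, ph, bsa) {
  n <- length(values)
  if (length(ph) != n || length(bsa) != n) stop("length mismatch")
  X <- cbind(1, ph, bsa)
  if (qr(X)$rank < 3L)
    stop("rank-deficient design: pH and BSA variation required")
  fit <- lm(values ~ ph + bsa)
  cf <- coef(fit)
  theo <- as.vector(X %*% cf[c("(Intercept)", "ph", "bsa")])
  degenerate <- var(theo) < .Machine$double.eps * max(1, mean(theo)^2)
  r2 <- if (degenerate) 0 else suppressWarnings(cor(theo, values)^2)
  if (!is.finite(r2)) { r2 <- 0; degenerate <- TRUE }
  list(alpha = cf[["ph"]], beta = cf[["bsa"]], epsilon = cf[["(Intercept)"]],
       theoretical = theo, r2 = r2, degenerate = degenerate)
}

#' Significance of a CEST-effect difference
#'
#' The difference between two measurements is significant when it exceeds
#' their standard deviations added in quadrature.
#'
#' @param a,b lists with `value` and `sd` (as returned by the metric
#'   pipeline).
#' @return list: `delta`, `sigma`, `significant`.
#' @export
deltaCestSignificance <- function(a, b) {
  delta <- a$value - b$value
  sigma <- sqrt(a$sd^2 + b$sd^2)
  list(delta = delta, sigma = sigma, significant = abs(delta) > sigma)
}

#' Back-calculate a pH difference from a CEST-effect difference
#'
#' Inverts the ideal-metric linear model:
#' `delta_pH = (delta_CEST - beta * delta_BSA) / alpha`.
#'
#' @param deltaCest CEST-effect difference (%M0).
#' @param deltaBsa BSA difference (% w/v) between the two samples.
#' @param model a [fitIdealModel()] result (uses `alpha`, `beta`).
#' @return pH difference (pH units).
#' @export
deltaPH <- function(deltaCest, deltaBsa, model) {
  if (!is.finite(model$alpha) || model$alpha == 0)
    stop("alpha must be nonzero to back-calculate pH")
  (deltaCest - model$beta * deltaBsa) / model$alpha
}

#' Pairwise pH-difference table
#'
#' For every pair of phantoms in the supplied table, computes the
#' CEST-effect difference, its quadrature significance, the back-calculated
#' pH difference for significant pairs, and whether its sign matches the
#' experimental pH difference.
#'
#' @param tab data.frame with columns `id`, `ph`, `bsa`, `value`, `sd`.
#' @param model a [fitIdealModel()] result.
#' @return data.frame, one row per pair.
#' @export
deltaPHPairs <- function(tab, model) {
  n <- nrow(tab)
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  out <- lapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 1]; j <- pairs[r, 2]  # delta = row i minus row j, i < j
    dc <- deltaCestSignificance(list(value = tab$value[i], sd = tab$sd[i]),
                                list(value = tab$value[j], sd = tab$sd[j]))
    calc <- if (dc$significant)
      deltaPH(dc$delta, tab$bsa[i] - tab$bsa[j], model) else NA_real_
    expdph <- tab$ph[i] - tab$ph[j]
    data.frame(id1 = tab$id[i], id2 = tab$id[j], deltaCest = dc$delta,
               sigmaDelta = dc$sigma, significant = dc$significant,
               calculatedDeltaPH = calc, experimentalDeltaPH = expdph,
               signCorrect = if (dc$significant)
                 sign(calc) == sign(expdph) else NA,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Sign accuracy of pH-difference predictions by effect-size group
#'
#' Groups pairs by the experimental pH difference (below `-threshold`,
#' within `+-threshold`, above `+threshold`) and reports, per group, the
#' fraction of significant pairs whose back-calculated pH difference has the
#' correct sign. Empty groups are reported as `NA`.
#'
#' @param pairs data.frame from [deltaPHPairs()].
#' @param threshold grouping threshold (pH units, default 0.6).
#' @return data.frame with `group`, `nSignificant`, `accuracy`.
#' @export
signAccuracy <- function(pairs, threshold = 0.6) {
  grp <- cut(pairs$experimentalDeltaPH,
             c(-Inf, -threshold, threshold, Inf), right = FALSE,
             labels = c("below", "middle", "above"))
  # boundary convention: |delta pH| exactly at threshold is an outer group
  grp[pairs$experimentalDeltaPH >= threshold] <- "above"
  out <- lapply(levels(grp), function(g) {
    sel <- pairs[grp == g & pairs$significant, , drop = FALSE]
    data.frame(group = g, nSignificant = nrow(sel),
               accuracy = if (nrow(sel)) 100 * mean(sel$signCorrect)
                          else NA_real_, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
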