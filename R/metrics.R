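# Non-model-based Z-spectrum metrics: B0 correction, MTRasym, APT*, MTRRex,
# AREX, and ROI statistics. All metric values are reported in %M0, i.e. 100x
# the normalized signal difference, so that regression coefficients are
# comparable across metrics.

#' Metric evaluation parameters
#'
#' @param omega target offset (ppm), the frequency of the labile pool.
#' @param delta flanking-offset spacing (ppm) for the three-offset reference
#'   `Zref = (Z(omega + delta) + Z(omega - delta))/2`.
#' @return list with class `"MetricParams"`.
#' @export
metricParams <- function(omega = 2.8, delta = 1.4) {
  if (delta <= 0) stop("delta must be > 0")
  structure(list(omega = omega, delta = delta), class = "MetricParams")
}

# normalized-signal interpolant; the sampled grid rarely contains the exact
# target offsets, so piecewise-cubic interpolation is used throughout
zInterp <- function(spec) {
  splinefun(spec@offsets, spec@signals / spec@z0, method = "natural")
}

checkRange <- function(spec, ppm) {
  if (min(ppm) < min(spec@offsets) || max(ppm) > max(spec@offsets))
    stop("requested offsets outside the sampled range")
}

#' B0 correction by minimum shift
#'
#' Locates the minimum of the Z spectrum on a spline interpolant within a
#' search window around 0 ppm and shifts the spectrum so the minimum sits at
#' 0 ppm, re-interpolating the signals onto the original offset grid. If the
#' located minimum lies on the window boundary, a warning is issued and no
#' shift is applied.
#'
#' @param spec a [ZSpectrum-class].
#' @param searchWindow half-width of the search window (ppm).
#' @return corrected [ZSpectrum-class] with `b0Shift` recorded.
#' @export
b0Correct <- function(spec, searchWindow = 1.5) {
  f <- zInterp(spec)
  win <- which(spec@offsets >= max(min(spec@offsets), -searchWindow) &
               spec@offsets <= min(max(spec@offsets), searchWindow))
  iMin <- win[which.min(spec@signals[win])]
  if (iMin == win[1] || iMin == win[length(win)]) {
    warning("Z-spectrum minimum on search-window boundary; no shift applied")
    shift <- 0
  } else {
    # sub-sample refinement around the sampled minimum; a global search on
    # the interpolant is unreliable when the water line is narrower than
    # the offset spacing
    shift <- optimize(f, spec@offsets[c(iMin - 1, iMin + 1)])$minimum
  }
  sig <- f(spec@offsets + shift) * spec@z0
  sig <- pmin(pmax(sig, -0.049 * spec@z0), 1.049 * spec@z0)
  zSpectrum(spec@offsets, sig, z0 = spec@z0,
            b0Shift = spec@b0Shift + shift)
}

#' MTRasym: asymmetry analysis
#'
#' `100 * (Z(-omega) - Z(omega)) / Z0` in %M0.
#'
#' @param spec a [ZSpectrum-class] (B0-corrected for real data).
#' @param p a [metricParams()] list.
#' @return metric value (%M0).
#' @examples
#' s <- zSpectrum(c(-2.8, 0, 2.8), c(0.70, 0.1, 0.60), z0 = 1)
#' mtrAsym(s, metricParams())  # 10
#' @export
mtrAsym <- function(spec, p = metricParams()) {
  if (spec@z0 <= 0) stop("z0 must be > 0")
  checkRange(spec, c(-p$omega, p$omega))
  f <- zInterp(spec)
  100 * (f(-p$omega) - f(p$omega))
}

zrefFlanking <- function(f, p, convention = c("mean", "difference")) {
  convention <- match.arg(convention)
  if (convention == "mean")
    (f(p$omega + p$delta) + f(p$omega - p$delta)) / 2
  else
    f(p$omega + p$delta) - f(p$omega - p$delta) / 2
}

#' APT*: three-offset analysis
#'
#' `100 * (Zref - Z(omega)) / Z0` with the flanking reference
#' `Zref = (Z(omega + delta) + Z(omega - delta))/2`. Negative values are
#' unphysical (they arise when water-line broadening leaves no discernible
#' CEST peak) and are clipped to zero unless `clip = FALSE`.
#'
#' @param spec a [ZSpectrum-class].
#' @param p a [metricParams()] list.
#' @param clip set negative values to 0 (default TRUE).
#' @param convention flanking-reference convention; `"mean"` (default) or the
#'   literal `"difference"` form retained for audit.
#' @return metric value (%M0).
#' @export
aptStar <- function(spec, p = metricParams(), clip = TRUE,
                    convention = "mean") {
  if (spec@z0 <= 0) stop("z0 must be > 0")
  checkRange(spec, c(p$omega - p$delta, p$omega + p$delta))
  f <- zInterp(spec)
  v <- 100 * (zrefFlanking(f, p, convention) - f(p$omega))
  if (clip) max(v, 0) else v
}

#' MTRRex: inverse-Z analysis
#'
#' `100 * (1/Z(omega) - 1/Zref)` on normalized signals, reported on the same
#' %M0 axis as the other metrics. Clipped at zero like [aptStar()].
#'
#' @inheritParams aptStar
#' @return metric value (%M0).
#' @export
mtrRex <- function(spec, p = metricParams(), clip = TRUE,
                   convention = "mean") {
  checkRange(spec, c(p$omega - p$delta, p$omega + p$delta))
  f <- zInterp(spec)
  zw <- f(p$omega)
  zr <- zrefFlanking(f, p, convention)
  if (zw <= 0) stop("Z(omega) <= 0: nonphysical normalized signal")
  if (zr <= 0) stop("Zref <= 0: nonphysical normalized signal")
  v <- 100 * (1 / zw - 1 / zr)
  if (clip) max(v, 0) else v
}

#' AREX: relaxation-compensated inverse-Z metric
#'
#' `MTRRex / T1` with the water T1 measured independently (units %M0 s^-1).
#'
#' @param mtrRexValue MTRRex value (%M0).
#' @param t1 water T1 (s, > 0).
#' @return metric value (%M0 s^-1).
#' @export
arex <- function(mtrRexValue, t1) {
  if (!is.finite(t1) || t1 <= 0) stop("t1 must be > 0")
  mtrRexValue / t1
}

#' ROI statistics
#'
#' Mean, sample (n-1) standard deviation and count over a region of interest.
#'
#' @param values per-voxel metric values.
#' @return list with `mean`, `sd` (0 when n = 1) and `n`.
#' @export
roiStatistics <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("empty ROI")
  list(mean = mean(values),
       sd = if (length(values) > 1L) sd(values) else 0,
       n = length(values))
}
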