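#' @import methods
#' @importFrom stats approx coef cor lm mad median optimize pt qt residuals
#'   rnorm sd setNames splinefun var
#' @importFrom utils head read.csv write.csv
#' @useDynLib cestr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' ExchangePool: one proton pool of a Bloch-McConnell spin system
#'
#' A labile proton pool is described by its chemical shift relative to water,
#' its exchange rate toward water, its proton fraction relative to water, and
#' its own relaxation times. The water pool itself has `fraction = 1` and
#' `rate = 0` by convention.
#'
#' @slot name pool label.
#' @slot offset chemical shift in ppm (water at 0; positive = downfield).
#' @slot rate exchange rate toward water in s^-1 (>= 0).
#' @slot fraction proton concentration relative to water (>= 0).
#' @slot t1 longitudinal relaxation time in s (> 0).
#' @slot t2 transverse relaxation time in s (> 0).
#' @export
setClass("ExchangePool",
  representation(name = "character", offset = "numeric", rate = "numeric",
                 fraction = "numeric", t1 = "numeric", t2 = "numeric"))

setValidity("ExchangePool", function(object) {
  msg <- character()
  num1 <- function(x) length(x) == 1L && is.finite(x)
  if (!num1(object@offset)) msg <- c(msg, "offset must be a finite scalar")
  if (!num1(object@rate) || object@rate < 0)
    msg <- c(msg, "rate must be a finite scalar >= 0")
  if (!num1(object@fraction) || object@fraction < 0)
    msg <- c(msg, "fraction must be a finite scalar >= 0")
  if (!num1(object@t1) || object@t1 <= 0) msg <- c(msg, "t1 must be > 0")
  if (!num1(object@t2) || object@t2 <= 0) msg <- c(msg, "t2 must be > 0")
  if (length(msg)) msg else TRUE
})

#' Create an exchange pool
#'
#' @param name pool label.
#' @param offset chemical shift (ppm from water).
#' @param rate exchange rate toward water (s^-1).
#' @param fraction proton fraction relative to water.
#' @param t1,t2 pool relaxation times (s). `t2 > t1` is physically unusual and
#'   triggers a warning but is not an error.
#' @return an [ExchangePool-class] object.
#' @examples
#' exchangePool("amine", offset = 2.8, rate = 1000, fraction = 5e-4,
#'              t1 = 1, t2 = 0.01)
#' @export
exchangePool <- function(name, offset, rate, fraction, t1, t2) {
  obj <- new("ExchangePool", name = as.character(name), offset = offset,
             rate = rate, fraction = fraction, t1 = t1, t2 = t2)
  if (t2 > t1)
    warning("pool '", name, "': t2 > t1 is physically unusual")
  obj
}

#' SpinSystem: an ordered collection of exchanging proton pools
#'
#' Water is always the first pool; all labile pools exchange with water only
#' (no labile-labile exchange). The Larmor frequency converts chemical shifts
#' in ppm to angular frequencies (rad/s) via `2*pi*larmor*ppm`.
#'
#' @slot pools list of [ExchangePool-class], water first.
#' @slot larmorFrequency scanner frequency in MHz (400 for a 9.4 T system).
#' @export
setClass("SpinSystem",
  representation(pools = "list", larmorFrequency = "numeric"))

setValidity("SpinSystem", function(object) {
  msg <- character()
  if (length(object@pools) < 1L ||
      !all(vapply(object@pools, is, TRUE, "ExchangePool")))
    msg <- c(msg, "pools must be a non-empty list of ExchangePool objects")
  else {
    w <- object@pools[[1L]]
    if (w@fraction != 1) msg <- c(msg, "water (first pool) must have fraction 1")
    if (w@rate != 0) msg <- c(msg, "water (first pool) must have rate 0")
  }
  if (length(object@larmorFrequency) != 1L || object@larmorFrequency <= 0)
    msg <- c(msg, "larmorFrequency must be a positive scalar (MHz)")
  if (length(msg)) msg else TRUE
})

#' Create a spin system
#'
#' @param water water [ExchangePool-class] (`fraction = 1`, `rate = 0`).
#' @param ... labile [ExchangePool-class] objects.
#' @param larmorFrequency Larmor frequency in MHz (default 400, i.e. 9.4 T).
#' @return a [SpinSystem-class].
#' @examples
#' sys <- spinSystem(
#'   waterPool(t1 = 1.7, t2 = 0.14),
#'   exchangePool("amine", 2.8, 1000, 5e-4, 1, 0.01))
#' @export
spinSystem <- function(water, ..., larmorFrequency = 400) {
  new("SpinSystem", pools = c(list(water), list(...)),
      larmorFrequency = larmorFrequency)
}

#' Water pool shorthand
#'
#' @param t1,t2 water relaxation times (s).
#' @return an [ExchangePool-class] with `fraction = 1`, `rate = 0`, offset 0.
#' @export
waterPool <- function(t1, t2) {
  new("ExchangePool", name = "water", offset = 0, rate = 0, fraction = 1,
      t1 = t1, t2 = t2)
}

#' SaturationScheme: CW or shaped-pulse-train RF saturation
#'
#' @slot mode `"cw"` or `"gaussian_train"`.
#' @slot nPulses number of pulses in the train.
#' @slot pulseDuration single-pulse duration (s).
#' @slot flipAngle per-pulse flip angle (degrees).
#' @slot dutyCycle fraction of each period with RF on, in (0, 1].
#' @slot cwB1 CW amplitude in uT (used when `mode = "cw"`).
#' @slot nSegments piecewise-constant segments per pulse.
#' @slot pulseShape `"gaussian"` (truncated at +-3 sigma, sigma = duration/6)
#'   or `"rect"`.
#' @slot offsets saturation offsets (ppm).
#' @slot referenceOffsets far-off-resonance offsets used for normalization.
#' @export
setClass("SaturationScheme",
  representation(mode = "character", nPulses = "numeric",
                 pulseDuration = "numeric", flipAngle = "numeric",
                 dutyCycle = "numeric", cwB1 = "numeric",
                 nSegments = "numeric", pulseShape = "character",
                 offsets = "numeric", referenceOffsets = "numeric"))

setValidity("SaturationScheme", function(object) {
  msg <- character()
  if (!object@mode %in% c("cw", "gaussian_train"))
    msg <- c(msg, "mode must be 'cw' or 'gaussian_train'")
  if (object@dutyCycle <= 0 || object@dutyCycle > 1)
    msg <- c(msg, "dutyCycle must be in (0, 1]")
  if (object@nSegments < 1) msg <- c(msg, "nSegments must be >= 1")
  if (!length(object@referenceOffsets))
    msg <- c(msg, "referenceOffsets must be non-empty")
  if (!object@pulseShape %in% c("gaussian", "rect"))
    msg <- c(msg, "pulseShape must be 'gaussian' or 'rect'")
  if (object@mode == "cw" && (length(object@cwB1) != 1L || object@cwB1 < 0))
    msg <- c(msg, "cw mode requires cwB1 >= 0")
  if (length(msg)) msg else TRUE
})

#' Create a saturation scheme
#'
#' Defaults reproduce a pulsed saturation train of 300 Gaussian pulses of
#' 26 ms duration and 180 degree flip angle at 50% duty cycle, sampled at 85
#' offsets evenly spaced in +-10 ppm with +-100 ppm reference scans.
#' `dutyCycle = 0.5` is interpreted as a 26 ms pulse followed by a 26 ms gap
#' (15.6 s total train); the alternative reading of a 7.8 s train is obtained
#' by setting `nPulses = 150`.
#'
#' @param mode `"cw"` or `"gaussian_train"`.
#' @param nPulses,pulseDuration,flipAngle,dutyCycle pulse-train parameters
#'   (unused for `mode = "cw"`).
#' @param cwB1 CW saturation amplitude (uT), for `mode = "cw"`.
#' @param nSegments piecewise-constant discretization per pulse.
#' @param pulseShape `"gaussian"` or `"rect"`.
#' @param offsets saturation offsets (ppm).
#' @param referenceOffsets normalization offsets (ppm).
#' @return a [SaturationScheme-class].
#' @export
saturationScheme <- function(mode = c("gaussian_train", "cw"), nPulses = 300,
                             pulseDuration = 0.026, flipAngle = 180,
                             dutyCycle = 0.5, cwB1 = NA_real_,
                             nSegments = 32, pulseShape = "gaussian",
                             offsets = seq(-10, 10, length.out = 85),
                             referenceOffsets = c(-100, 100)) {
  mode <- match.arg(mode)
  if (mode == "cw" && is.na(cwB1))
    stop("cw mode requires cwB1")
  new("SaturationScheme", mode = mode, nPulses = nPulses,
      pulseDuration = pulseDuration, flipAngle = flipAngle,
      dutyCycle = dutyCycle, cwB1 = if (is.na(cwB1)) 0 else cwB1,
      nSegments = nSegments, pulseShape = pulseShape, offsets = offsets,
      referenceOffsets = referenceOffsets)
}

#' ZSpectrum: normalized saturation-offset/signal pairs
#'
#' Signals are water Mz/M0 following saturation at each offset; `z0` is the
#' reference signal following far-off-resonance saturation, the normalizer
#' used by all metrics. `b0Shift` records any applied B0 correction (ppm).
#'
#' @slot offsets saturation offsets (ppm), strictly increasing.
#' @slot signals water signal after saturation (same length as offsets).
#' @slot z0 reference signal (> 0).
#' @slot b0Shift applied B0 shift correction (ppm), 0 until corrected.
#' @export
setClass("ZSpectrum",
  representation(offsets = "numeric", signals = "numeric", z0 = "numeric",
                 b0Shift = "numeric"))

setValidity("ZSpectrum", function(object) {
  msg <- character()
  if (length(object@offsets) != length(object@signals))
    msg <- c(msg, "offsets and signals must have equal length")
  if (length(object@offsets) && any(diff(object@offsets) <= 0))
    msg <- c(msg, "offsets must be strictly increasing")
  if (length(object@z0) != 1L || !is.finite(object@z0) || object@z0 <= 0)
    msg <- c(msg, "z0 must be a positive scalar")
  if (length(object@signals) &&
      (min(object@signals) < -0.05 * object@z0 ||
       max(object@signals) > 1.05 * object@z0))
    msg <- c(msg, "signals outside [-0.05, 1.05] of z0")
  if (length(msg)) msg else TRUE
})

#' Create a Z spectrum
#'
#' @param offsets saturation offsets (ppm); reordered to be increasing.
#' @param signals water signals after saturation.
#' @param z0 far-off-resonance reference signal.
#' @param b0Shift applied B0 correction (ppm).
#' @return a [ZSpectrum-class].
#' @export
zSpectrum <- function(offsets, signals, z0 = 1, b0Shift = 0) {
  ord <- order(offsets)
  new("ZSpectrum", offsets = offsets[ord], signals = signals[ord], z0 = z0,
      b0Shift = b0Shift)
}

#' CESTPriors: prior distributions for the three-pool model fit
#'
#' Water relaxation priors are normal; exchange rates and fractions are
#' log-normal (normal on log10); the B0 shift prior is normal. Non-water pool
#' relaxation times are treated as fixed constants during fitting.
#'
#' @slot waterT1Mean,waterT1Sd water T1 prior (s).
#' @slot waterT2Mean,waterT2Sd water T2 prior (s).
#' @slot poolPriors data.frame with columns `name`, `offset` (ppm),
#'   `logRateMean`, `logRateSd`, `logFracMean`, `logFracSd` (log10 units),
#'   `t1`, `t2` (fixed pool relaxation, s).
#' @slot b0Mean,b0Sd B0 shift prior (ppm).
#' @export
setClass("CESTPriors",
  representation(waterT1Mean = "numeric", waterT1Sd = "numeric",
                 waterT2Mean = "numeric", waterT2Sd = "numeric",
                 poolPriors = "data.frame", b0Mean = "numeric",
                 b0Sd = "numeric"))

setValidity("CESTPriors", function(object) {
  msg <- character()
  if (object@waterT1Mean <= 0 || object@waterT2Mean <= 0)
    msg <- c(msg, "water T1/T2 prior means must be > 0")
  if (object@waterT1Sd <= 0 || object@waterT2Sd <= 0 || object@b0Sd <= 0)
    msg <- c(msg, "prior sds must be > 0")
  need <- c("name", "offset", "logRateMean", "logRateSd", "logFracMean",
            "logFracSd", "t1", "t2")
  if (!all(need %in% names(object@poolPriors)))
    msg <- c(msg, paste("poolPriors must have columns:",
                        paste(need, collapse = ", ")))
  else if (any(object@poolPriors$logRateSd <= 0) ||
           any(object@poolPriors$logFracSd <= 0))
    msg <- c(msg, "pool prior sds must be > 0")
  if (length(msg)) msg else TRUE
})

#' CESTFit: result of fitting the three-pool model to a Z spectrum
#'
#' @slot estimates named numeric: per-pool `rate_<name>` (s^-1) and
#'   `fraction_<name>`, plus `t1_water` (s), `t2_water` (s), `b0` (ppm).
#' @slot se named numeric of the same length: approximate posterior standard
#'   deviations (on log10 scale for rates/fractions).
#' @slot kfProduct fitted rate x fraction product of the CEST pool (s^-1).
#' @slot kfLogSd posterior sd of log10(rate x fraction) of the CEST pool.
#' @slot r2 goodness of fit on the spectrum (1 - SSres/SStot).
#' @slot converged logical convergence flag.
#' @slot nStarts number of optimization starts used.
#' @slot details list of diagnostics (objective, covariance, noise sd, ...).
#' @export
setClass("CESTFit",
  representation(estimates = "numeric", se = "numeric", kfProduct = "numeric",
                 kfLogSd = "numeric", r2 = "numeric", converged = "logical",
                 nStarts = "numeric", details = "list"))

setValidity("CESTFit", function(object) {
  msg <- character()
  if (is.finite(object@r2) && object@r2 > 1) msg <- c(msg, "r2 must be <= 1")
  if (any(object@se < 0, na.rm = TRUE)) msg <- c(msg, "se must be >= 0")
  if (length(msg)) msg else TRUE
})

#' CESTStudy: a realized synthetic phantom study
#'
#' @slot design data.frame of phantom specifications (one row per phantom).
#' @slot spectra named list; per phantom a list of voxel [ZSpectrum-class]
#'   replicates.
#' @slot relaxometry named list; per phantom the inversion-recovery and
#'   spin-echo series.
#' @slot groundTruth data.frame of generating pool parameters per phantom.
#' @slot scheme the [SaturationScheme-class] used.
#' @slot seed RNG seed used for realization.
#' @slot noiseSd Z-spectrum noise sd (fraction of z0).
#' @export
setClass("CESTStudy",
  representation(design = "data.frame", spectra = "list",
                 relaxometry = "list", groundTruth = "data.frame",
                 scheme = "SaturationScheme", seed = "numeric",
                 noiseSd = "numeric"))

# ---- accessors ----

#' Accessors for core objects
#'
#' `offsets()`, `signals()`, `z0()` and `b0Shift()` access [ZSpectrum-class]
#' slots; `pools()` and `larmorFrequency()` access [SpinSystem-class] slots;
#' `normalizedSignals()` returns `signals/z0`.
#'
#' @param object a package object.
#' @return the slot value.
#' @name accessors
#' @aliases offsets signals z0 b0Shift pools larmorFrequency
#'   normalizedSignals
NULL

#' @rdname accessors
#' @export
setGeneric("offsets", function(object) standardGeneric("offsets"))
#' @rdname accessors
#' @export
setGeneric("signals", function(object) standardGeneric("signals"))
#' @rdname accessors
#' @export
setGeneric("z0", function(object) standardGeneric("z0"))
#' @rdname accessors
#' @export
setGeneric("b0Shift", function(object) standardGeneric("b0Shift"))
#' @rdname accessors
#' @export
setGeneric("pools", function(object) standardGeneric("pools"))
#' @rdname accessors
#' @export
setGeneric("larmorFrequency", function(object)
  standardGeneric("larmorFrequency"))
#' @rdname accessors
#' @export
setGeneric("normalizedSignals", function(object)
  standardGeneric("normalizedSignals"))

#' @rdname accessors
setMethod("offsets", "ZSpectrum", function(object) object@offsets)
#' @rdname accessors
setMethod("signals", "ZSpectrum", function(object) object@signals)
#' @rdname accessors
setMethod("z0", "ZSpectrum", function(object) object@z0)
#' @rdname accessors
setMethod("b0Shift", "ZSpectrum", function(object) object@b0Shift)
#' @rdname accessors
setMethod("normalizedSignals", "ZSpectrum",
          function(object) object@signals / object@z0)
#' @rdname accessors
setMethod("pools", "SpinSystem", function(object) object@pools)
#' @rdname accessors
setMethod("larmorFrequency", "SpinSystem",
          function(object) object@larmorFrequency)

#' @rdname accessors
#' @export
setGeneric("fitEstimates", function(object) standardGeneric("fitEstimates"))
#' @rdname accessors
setMethod("fitEstimates", "CESTFit", function(object) object@estimates)

#' @rdname accessors
#' @export
setGeneric("studyDesign", function(object) standardGeneric("studyDesign"))
#' @rdname accessors
setMethod("studyDesign", "CESTStudy", function(object) object@design)

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))
#' @rdname accessors
setMethod("groundTruth", "CESTStudy", function(object) object@groundTruth)

# internal: pool parameter matrix for the C++ kernels
poolMatrix <- function(system) {
  p <- system@pools
  m <- t(vapply(p, function(x)
    c(x@offset, x@rate, x@fraction, x@t1, x@t2), numeric(5)))
  dimnames(m) <- list(vapply(p, function(x) x@name, character(1)),
                      c("offset", "rate", "fraction", "t1", "t2"))
  m
}

# ---- show methods ----

setMethod("show", "ExchangePool", function(object) {
  cat(sprintf(
    "ExchangePool '%s': %+0.2f ppm, k = %.4g /s, f = %.3g, T1 = %.3g s, T2 = %.3g s\n",
    object@name, object@offset, object@rate, object@fraction, object@t1,
    object@t2))
})

setMethod("show", "SpinSystem", function(object) {
  cat(sprintf("SpinSystem with %d pool(s) at %.0f MHz\n",
              length(object@pools), object@larmorFrequency))
  for (p in object@pools) show(p)
})

setMethod("show", "SaturationScheme", function(object) {
  if (object@mode == "cw") {
    cat(sprintf("SaturationScheme: CW, B1 = %.3g uT", object@cwB1))
  } else {
    cat(sprintf(
      "SaturationScheme: %d %s pulses x %.0f ms, flip %.0f deg, duty %.0f%%",
      object@nPulses, object@pulseShape, 1000 * object@pulseDuration,
      object@flipAngle, 100 * object@dutyCycle))
  }
  cat(sprintf("; %d offsets in [%.3g, %.3g] ppm, refs at %s ppm\n",
              length(object@offsets), min(object@offsets),
              max(object@offsets),
              paste(object@referenceOffsets, collapse = "/")))
})

setMethod("show", "ZSpectrum", function(object) {
  cat(sprintf(
    "ZSpectrum: %d offsets in [%.3g, %.3g] ppm, z0 = %.4g, b0 shift = %.3g ppm\n",
    length(object@offsets), min(object@offsets), max(object@offsets),
    object@z0, object@b0Shift))
})

setMethod("show", "CESTFit", function(object) {
  cat(sprintf("CESTFit: R2 = %.4f, %sconverged (%d start(s))\n", object@r2,
              if (object@converged) "" else "NOT ", object@nStarts))
  cat(sprintf("  CEST pool rate x fraction = %.4g /s (log10 sd %.2g)\n",
              object@kfProduct, object@kfLogSd))
  cat(sprintf("  water T1 = %.3g s, T2 = %.3g s, B0 shift = %.3g ppm\n",
              object@estimates["t1_water"], object@estimates["t2_water"],
              object@estimates["b0"]))
})

setMethod("show", "CESTStudy", function(object) {
  cat(sprintf(
    "CESTStudy: %d phantoms (%s), noise sd %.3g, seed %d\n",
    nrow(object@design),
    paste(sprintf("%s n=%d", names(table(object@design$model)),
                  as.integer(table(object@design$model))), collapse = ", "),
    object@noiseSd, as.integer(object@seed)))
})
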