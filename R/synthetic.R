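# Synthetic phantom study generator: spin systems from (pH, BSA, T1, T2)
# specifications, the 52-phantom two-model factorial design, noisy Z spectra,
# relaxometry series and optional image-grid realizations. This stands in
# for the undeposited phantom MRI data and carries its generating ground
# truth for recovery tests.

synthDefaults <- function() {
  list(kRef = c(tumour = 1100, brain = 900),  # amine rate at pH 7.4 (s^-1)
       kNoe = 20,                              # pH-independent (s^-1)
       fAmineRef = 3e-3, fNoeRef = 2e-3,       # fractions at 8% w/v BSA
       aminePool = c(offset = 2.8, t1 = 1.0, t2 = 0.010),
       noePool = c(offset = -3.5, t1 = 1.0, t2 = 0.005),
       baseline = c(ph = 7.4, bsa = 8, t1 = 1.7, t2 = 0.140))
}

#' Map pH to labile-proton exchange rate
#'
#' The amine pool follows pure base catalysis with one decade of rate per pH
#' unit, anchored at the model-specific reference rate at pH 7.4; the
#' -3.5 ppm pool rate is pH-independent.
#'
#' @param ph pH value.
#' @param pool `"amine"` or `"noe"`.
#' @param model `"tumour"` or `"brain"` (distinct amine reference rates).
#' @return exchange rate (s^-1).
#' @examples
#' phToRate(7.4, "amine", "tumour")           # reference rate
#' phToRate(6.4, "amine", "tumour")           # one decade slower
#' @export
phToRate <- function(ph, pool = c("amine", "noe"),
                     model = c("tumour", "brain")) {
  pool <- match.arg(pool)
  model <- match.arg(model)
  d <- synthDefaults()
  if (pool == "noe") return(d$kNoe)
  unname(d$kRef[model] * 10^(ph - 7.4))
}

#' Map BSA concentration to labile-proton fraction
#'
#' Linear in protein concentration, anchored at 8% w/v.
#'
#' @param bsa BSA concentration (% w/v, > 0).
#' @param pool `"amine"` or `"noe"`.
#' @return proton fraction relative to water.
#' @export
bsaToFraction <- function(bsa, pool = c("amine", "noe")) {
  pool <- match.arg(pool)
  if (any(bsa <= 0)) stop("bsa must be > 0")
  d <- synthDefaults()
  fRef <- if (pool == "amine") d$fAmineRef else d$fNoeRef
  fRef * bsa / 8
}

#' Spin system for one phantom specification
#'
#' @param ph,bsa,t1,t2 phantom composition and water relaxation (s).
#' @param model `"tumour"` or `"brain"`.
#' @param larmor Larmor frequency (MHz).
#' @return a [SpinSystem-class] with water, amine (+2.8 ppm) and NOE
#'   (-3.5 ppm) pools.
#' @export
phantomSystem <- function(ph, bsa, t1, t2, model = c("tumour", "brain"),
                          larmor = 400) {
  model <- match.arg(model)
  d <- synthDefaults()
  a <- d$aminePool
  n <- d$noePool
  spinSystem(
    waterPool(t1 = t1, t2 = t2),
    exchangePool("amine", a[["offset"]], phToRate(ph, "amine", model),
                 bsaToFraction(bsa, "amine"), a[["t1"]], a[["t2"]]),
    exchangePool("noe", n[["offset"]], phToRate(ph, "noe", model),
                 bsaToFraction(bsa, "noe"), n[["t1"]], n[["t2"]]),
    larmorFrequency = larmor)
}

#' Build the full factorial study design
#'
#' Two phantom models (tumour, naive brain) x 26 phantoms each: serial
#' variation of pH (6.0-7.6, n = 6), BSA (4-16% w/v, n = 7), T1 (0.3-1.7 s,
#' n = 7) and T2 (29-140 ms, n = 6), evenly spaced, all other parameters at
#' the baseline (pH 7.4, 8% w/v BSA, T1 1.7 s, T2 140 ms).
#'
#' @param crossEffect reproduce the contrast-agent cross-relaxation effect
#'   (the agent used to shorten one relaxation time also shortens the other:
#'   ~18% T1 change across the T2 arm, ~34% T2 change across the T1 arm).
#'   Default `FALSE` (relaxation times treated as independent).
#' @return data.frame with one row per phantom: `id`, `model`,
#'   `varied_parameter`, `ph`, `bsa`, `t1`, `t2`.
#' @export
buildDesign <- function(crossEffect = FALSE) {
  d <- synthDefaults()
  b <- d$baseline
  arms <- list(
    ph = seq(6.0, 7.6, length.out = 6),
    bsa = seq(4, 16, length.out = 7),
    t1 = seq(0.3, 1.7, length.out = 7),
    t2 = seq(0.029, 0.140, length.out = 6))
  rows <- list()
  for (model in c("tumour", "brain")) {
    for (arm in names(arms)) {
      vals <- arms[[arm]]
      prog <- (rev(seq_along(vals)) - 1) / (length(vals) - 1)
      for (i in seq_along(vals)) {
        spec <- as.list(b)
        spec[[arm]] <- vals[i]
        if (crossEffect) {
          if (arm == "t2") spec$t1 <- b[["t1"]] * (1 - 0.18 * prog[i])
          if (arm == "t1") spec$t2 <- b[["t2"]] * (1 - 0.34 * prog[i])
        }
        rows[[length(rows) + 1L]] <- data.frame(
          id = sprintf("%s_%s_%d", model, arm, i), model = model,
          varied_parameter = arm, ph = spec$ph, bsa = spec$bsa,
          t1 = spec$t1, t2 = spec$t2, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# raw (unnormalized) signals at scheme offsets plus reference offsets
simulateRawSignals <- function(system, scheme) {
  all <- c(scheme@offsets, scheme@referenceOffsets)
  z <- if (scheme@mode == "cw") {
    cwSteadyState(system, scheme@cwB1, all)
  } else {
    seg <- pulseSegments(scheme)
    as.vector(.zspecPulsedCpp(poolMatrix(system), system@larmorFrequency,
                              all, seg$b1, seg$dt, seg$gap,
                              as.integer(scheme@nPulses)))
  }
  n <- length(scheme@offsets)
  list(z = z[seq_len(n)], refs = z[-seq_len(n)])
}

#' Realize a synthetic phantom study
#'
#' For each phantom in the design: builds the spin system, simulates the
#' noise-free Z spectrum and reference scans, then draws `voxelsPerROI`
#' voxel replicates with additive Gaussian noise on the normalized signals
#' (both spectrum and reference scans), and generates inversion-recovery and
#' spin-echo relaxometry series with proportional Gaussian noise. The
#' generating ground truth is stored alongside the data.
#'
#' @param design data.frame from [buildDesign()].
#' @param scheme a [SaturationScheme-class] (default: the emulated pulsed
#'   acquisition).
#' @param seed RNG seed (fixed and recorded; same seed, same dataset).
#' @param noiseSd Gaussian noise sd on normalized Z signals (default 0.005).
#' @param voxelsPerROI noisy voxel replicates per phantom ROI.
#' @param relaxNoise relaxometry noise sd as a fraction of M0.
#' @param larmor Larmor frequency (MHz).
#' @return a [CESTStudy-class].
#' @export
realizeStudy <- function(design = buildDesign(),
                         scheme = saturationScheme(), seed = 1,
                         noiseSd = 0.005, voxelsPerROI = 5,
                         relaxNoise = 0.01, larmor = 400) {
  set.seed(seed)
  grids <- relaxometryGrids()
  spectra <- list()
  relax <- list()
  gt <- list()
  for (i in seq_len(nrow(design))) {
    ph <- design[i, ]
    sys <- phantomSystem(ph$ph, ph$bsa, ph$t1, ph$t2, ph$model, larmor)
    raw <- simulateRawSignals(sys, scheme)
    vox <- lapply(seq_len(voxelsPerROI), function(v) {
      sig <- raw$z + if (noiseSd > 0) rnorm(length(raw$z), 0, noiseSd) else 0
      refs <- raw$refs +
        if (noiseSd > 0) rnorm(length(raw$refs), 0, noiseSd) else 0
      sig <- pmin(pmax(sig, -0.049), 1.049)
      zSpectrum(scheme@offsets, sig, z0 = mean(refs))
    })
    irClean <- abs(1 - 2 * exp(-grids$ti / ph$t1))
    seClean <- exp(-grids$te / ph$t2)
    ir <- relaxSeries("inversion_recovery", grids$ti,
                      abs(irClean + rnorm(length(grids$ti), 0, relaxNoise)))
    se <- relaxSeries("spin_echo", grids$te,
                      pmax(seClean + rnorm(length(grids$te), 0, relaxNoise),
                           1e-6))
    spectra[[ph$id]] <- vox
    relax[[ph$id]] <- list(ir = ir, se = se)
    gt[[i]] <- data.frame(
      id = ph$id, kAmine = phToRate(ph$ph, "amine", ph$model),
      fAmine = bsaToFraction(ph$bsa, "amine"),
      kNoe = phToRate(ph$ph, "noe", ph$model),
      fNoe = bsaToFraction(ph$bsa, "noe"), t1 = ph$t1, t2 = ph$t2,
      stringsAsFactors = FALSE)
  }
  new("CESTStudy", design = design, spectra = spectra, relaxometry = relax,
      groundTruth = do.call(rbind, gt), scheme = scheme, seed = seed,
      noiseSd = noiseSd)
}

#' Paint per-phantom values into an image grid
#'
#' Places disc-like (plus-shaped, 5-voxel) ROIs for up to 26 phantoms on a
#' square image grid, emulating the multi-phantom acquisition layout.
#'
#' @param values per-phantom values (length <= 26).
#' @param matrixSize image matrix size (default 32).
#' @return list with `image` (value matrix, NA background) and `labels`
#'   (integer ROI label matrix, 0 background).
#' @export
paintStudyImage <- function(values, matrixSize = 32) {
  nPh <- length(values)
  if (nPh > 26) stop("at most 26 ROIs supported")
  img <- matrix(NA_real_, matrixSize, matrixSize)
  lab <- matrix(0L, matrixSize, matrixSize)
  nCol <- 6
  nRow <- ceiling(26 / nCol)
  cx <- round(seq(3, matrixSize - 2, length.out = nCol))
  cy <- round(seq(3, matrixSize - 2, length.out = nRow))
  for (i in seq_len(nPh)) {
    r <- cy[(i - 1) %/% nCol + 1]
    c <- cx[(i - 1) %% nCol + 1]
    idx <- rbind(c(r, c), c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))
    img[idx] <- values[i]
    lab[idx] <- i
  }
  list(image = img, labels = lab)
}
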