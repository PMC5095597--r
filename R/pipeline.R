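# End-to-end driver for the synthetic study and file-format adapters.

metricNames <- function() {
  c("MTRasym", "APTstar", "MTRRex", "AREX", "CESTRstar_default",
    "CESTRstar_measured")
}

#' Default run configuration
#'
#' @return named list of pipeline settings; any subset can be overridden via
#'   the `config` argument of [runFullStudy()] or a YAML file read with
#'   [readRunConfig()].
#' @export
defaultConfig <- function() {
  list(noiseSd = 0.005, voxelsPerROI = 5, relaxNoise = 0.01, omega = 2.8,
       delta = 1.4, familySize = 24, larmor = 400, crossEffect = FALSE,
       deltaMetric = "CESTRstar_measured", signThreshold = 0.6,
       fitMaxStarts = 3, maxRefine = 6, b0SearchWindow = 1.5)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; keys override [defaultConfig()].
#' @return merged configuration list.
#' @export
readRunConfig <- function(path) {
  cfg <- defaultConfig()
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  cfg
}

# per-phantom metric table rows from voxel spectra + fits
phantomMetrics <- function(vox, t1Meas, scheme, cfg, fitDef, fitMeas) {
  p <- metricParams(cfg$omega, cfg$delta)
  asym <- apt <- rex <- arx <- numeric(length(vox))
  for (v in seq_along(vox)) {
    s <- b0Correct(vox[[v]], cfg$b0SearchWindow)
    asym[v] <- mtrAsym(s, p)
    apt[v] <- aptStar(s, p, clip = FALSE)
    rex[v] <- mtrRex(s, p, clip = FALSE)
    arx[v] <- arex(rex[v], t1Meas)
  }
  direct <- list(MTRasym = asym, APTstar = apt, MTRRex = rex, AREX = arx)
  rows <- lapply(names(direct), function(m) {
    st <- roiStatistics(direct[[m]])
    # negative mean effects are unphysical; clip after ROI averaging
    val <- if (m == "MTRasym") st$mean else max(st$mean, 0)
    data.frame(metric = m, value = val, sd = st$sd, n = st$n,
               stringsAsFactors = FALSE)
  })
  cs <- list(
    CESTRstar_default = cestrStar(fitDef, scheme, p, larmor = cfg$larmor),
    CESTRstar_measured = cestrStar(fitMeas, scheme, p, larmor = cfg$larmor))
  rows <- c(rows, lapply(names(cs), function(m)
    data.frame(metric = m, value = cs[[m]]$value, sd = cs[[m]]$sd, n = 1L,
               stringsAsFactors = FALSE)))
  do.call(rbind, rows)
}

#' Run the full synthetic phantom study
#'
#' Orchestrates the complete pipeline: realize the 52-phantom study, fit the
#' relaxometry series, compute the four direct metrics per voxel with B0
#' correction and ROI statistics, fit the three-pool model per phantom with
#' default and with measured water-relaxation priors, derive both CESTR*
#' variants, and run the statistical comparison (per-parameter regressions,
#' Holm-Sidak-corrected cross-model slope tests, ideal-metric specificity
#' R-squared per metric, and the pairwise pH-difference analysis). The
#' result is deterministic given `seed` and `config`.
#'
#' @param seed RNG seed for the study realization.
#' @param config list overriding [defaultConfig()] entries, or a YAML path.
#' @param design optional design data.frame (default [buildDesign()]).
#' @param scheme optional [SaturationScheme-class].
#' @return list with elements `study`, `relaxometry`, `fits`, `metrics`,
#'   `regressions`, `slopeComparisons`, `specificity`, `deltaPH`, `config`.
#' @export
runFullStudy <- function(seed = 1, config = list(), design = NULL,
                         scheme = NULL) {
  cfg <- if (is.character(config)) readRunConfig(config)
         else utils::modifyList(defaultConfig(), config)
  if (is.null(design)) design <- buildDesign(cfg$crossEffect)
  if (is.null(scheme)) scheme <- saturationScheme()

  study <- realizeStudy(design, scheme, seed = seed, noiseSd = cfg$noiseSd,
                        voxelsPerROI = cfg$voxelsPerROI,
                        relaxNoise = cfg$relaxNoise, larmor = cfg$larmor)

  relaxFits <- lapply(study@relaxometry, function(r)
    list(t1 = fitT1IR(r$ir), t2 = fitT2SE(r$se)))

  fits <- list()
  metricRows <- list()
  for (i in seq_len(nrow(design))) {
    id <- design$id[i]
    vox <- study@spectra[[id]]
    t1m <- relaxFits[[id]]$t1$t1
    t2m <- relaxFits[[id]]$t2$t2
    roiSpec <- zSpectrum(
      offsets(vox[[1]]),
      rowMeans(vapply(vox, signals, numeric(length(offsets(vox[[1]]))))),
      z0 = mean(vapply(vox, z0, numeric(1))))
    fitDef <- fitZSpectrum(roiSpec, scheme, defaultPriors(),
                           larmor = cfg$larmor, maxStarts = cfg$fitMaxStarts,
                           maxRefine = cfg$maxRefine)
    fitMeas <- fitZSpectrum(roiSpec, scheme, measuredPriors(t1m, t2m),
                            larmor = cfg$larmor,
                            maxStarts = cfg$fitMaxStarts,
                            maxRefine = cfg$maxRefine)
    fits[[id]] <- list(default = fitDef, measured = fitMeas)
    mr <- phantomMetrics(vox, t1m, scheme, cfg, fitDef, fitMeas)
    mr <- cbind(design[rep(i, nrow(mr)), , drop = FALSE],
                t1Measured = t1m, t2Measured = t2m, mr)
    metricRows[[id]] <- mr
  }
  metrics <- do.call(rbind, metricRows)
  rownames(metrics) <- NULL

  regressions <- regressionTable(metrics)
  slopeComp <- slopeComparisonTable(regressions, cfg$familySize)
  spec <- specificityTable(metrics)
  dph <- deltaPHAnalysis(metrics, spec, cfg)

  list(study = study, relaxometry = relaxFits, fits = fits,
       metrics = metrics, regressions = regressions,
       slopeComparisons = slopeComp, specificity = spec, deltaPH = dph,
       config = c(cfg, seed = seed))
}

# Table-1 analog: per model x varied parameter x metric OLS results
regressionTable <- function(metrics) {
  rows <- list()
  for (model in unique(metrics$model)) {
    for (arm in unique(metrics$varied_parameter)) {
      sub0 <- metrics[metrics$model == model &
                      metrics$varied_parameter == arm, ]
      for (m in unique(metrics$metric)) {
        sub <- sub0[sub0$metric == m, ]
        rr <- regressMetric(sub$value, sub[[arm]])
        rows[[length(rows) + 1L]] <- data.frame(
          model = model, parameter = arm, metric = m, slope = rr$slope,
          se = rr$se, p = rr$p, n = rr$n, df = rr$df,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# Table-2 analog: cross-model slope comparisons, Holm-Sidak corrected
slopeComparisonTable <- function(regressions, familySize = 24) {
  arms <- unique(regressions$parameter)
  mets <- unique(regressions$metric)
  rows <- list()
  for (arm in arms) {
    for (m in mets) {
      a <- regressions[regressions$model == "tumour" &
                       regressions$parameter == arm &
                       regressions$metric == m, ]
      b <- regressions[regressions$model == "brain" &
                       regressions$parameter == arm &
                       regressions$metric == m, ]
      if (!nrow(a) || !nrow(b)) next  # single-model design: nothing to compare
      cs <- compareSlopes(as.list(a), as.list(b), familySize)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = arm, metric = m, t = cs$t, df = cs$df, p = cs$p,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(parameter = character(), metric = character(),
                      t = numeric(), df = numeric(), p = numeric(),
                      pAdjusted = numeric(), significant = logical()))
  out <- do.call(rbind, rows)
  out$pAdjusted <- holmSidakAdjust(out$p, m = max(familySize, nrow(out)))
  out$significant <- out$pAdjusted < 0.05
  out
}

# ideal-model fit and specificity R2 per metric, pooled over both models
specificityTable <- function(metrics) {
  rows <- list()
  fits <- list()
  for (m in unique(metrics$metric)) {
    sub <- metrics[metrics$metric == m, ]
    f <- fitIdealModel(sub$value, sub$ph, sub$bsa)
    fits[[m]] <- f
    rows[[length(rows) + 1L]] <- data.frame(
      metric = m, alpha = f$alpha, beta = f$beta, epsilon = f$epsilon,
      r2 = f$r2, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$r2), ]
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

# pairwise pH differences on the pH arm using the configured metric
deltaPHAnalysis <- function(metrics, spec, cfg) {
  m <- cfg$deltaMetric
  tab <- metrics[metrics$metric == m &
                 metrics$varied_parameter == "ph",
                 c("id", "ph", "bsa", "value", "sd")]
  model <- attr(spec, "fits")[[m]]
  pairs <- deltaPHPairs(tab, model)
  sig <- pairs[pairs$significant, ]
  rmsd <- if (nrow(sig))
    sqrt(mean((sig$calculatedDeltaPH - sig$experimentalDeltaPH)^2))
  else NA_real_
  list(pairs = pairs, rmsd = rmsd,
       signAccuracy = signAccuracy(pairs, cfg$signThreshold))
}

#' Compact numeric summary of a study report
#'
#' @param report result of [runFullStudy()].
#' @return named list of the headline quantities: specificity R-squared per
#'   metric, the top-ranked metric, tumour-arm pH slopes/p-values for the
#'   direct metrics, T1/T2-arm p-values for all metrics, pH-difference RMSD
#'   and per-group sign accuracies.
#' @export
studySummary <- function(report) {
  sp <- report$specificity
  reg <- report$regressions
  getp <- function(model, arm, metric)
    reg$p[reg$model == model & reg$parameter == arm & reg$metric == metric]
  gets <- function(model, arm, metric)
    reg$slope[reg$model == model & reg$parameter == arm &
              reg$metric == metric]
  sa <- report$deltaPH$signAccuracy
  list(
    specificityR2 = setNames(sp$r2, sp$metric),
    topMetric = sp$metric[1],
    tumourPhSlopes = vapply(c("MTRasym", "APTstar", "MTRRex"),
                            function(m) gets("tumour", "ph", m), 0),
    tumourPhP = vapply(c("MTRasym", "APTstar", "MTRRex"),
                       function(m) getp("tumour", "ph", m), 0),
    t1P = vapply(metricNames(), function(m) getp("tumour", "t1", m), 0),
    t2P = vapply(metricNames(), function(m) getp("tumour", "t2", m), 0),
    deltaPhRmsd = report$deltaPH$rmsd,
    signAccuracy = setNames(sa$accuracy, sa$group))
}

# ---- file-format adapters ----

#' Write / read a Z spectrum as CSV
#'
#' Two columns (`offset_ppm`, `signal`) with `z0` and `b0_shift` stored in
#' header comments; `readZSpectrum(writeZSpectrum(x))` is the identity.
#'
#' @param spec a [ZSpectrum-class].
#' @param path file path.
#' @return `readZSpectrum` returns a [ZSpectrum-class];
#'   `writeZSpectrum` returns `path` invisibly.
#' @export
writeZSpectrum <- function(spec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# z0 = %.17g", spec@z0), con)
  writeLines(sprintf("# b0_shift = %.17g", spec@b0Shift), con)
  writeLines("offset_ppm,signal", con)
  writeLines(sprintf("%.17g,%.17g", spec@offsets, spec@signals), con)
  invisible(path)
}

#' @rdname writeZSpectrum
#' @export
readZSpectrum <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getNum <- function(key) {
    ln <- grep(paste0("^# *", key, " *="), hdr, value = TRUE)
    if (!length(ln)) stop("missing '", key, "' header in ", path)
    as.numeric(sub(".*= *", "", ln[1]))
  }
  dat <- read.csv(text = lines[!grepl("^#", lines)])
  if (!all(c("offset_ppm", "signal") %in% names(dat)))
    stop("expected columns offset_ppm, signal in ", path)
  zSpectrum(dat$offset_ppm, dat$signal, z0 = getNum("z0"),
            b0Shift = getNum("b0_shift"))
}

#' Serialize a saturation scheme or spin system to YAML
#'
#' @param object a [SaturationScheme-class] or [SpinSystem-class].
#' @param path YAML file path.
#' @return `path`, invisibly.
#' @export
writeSchemeYaml <- function(object, path) {
  stopifnot(is(object, "SaturationScheme"))
  yaml::write_yaml(list(
    mode = object@mode, nPulses = object@nPulses,
    pulseDuration = object@pulseDuration, flipAngle = object@flipAngle,
    dutyCycle = object@dutyCycle, cwB1 = object@cwB1,
    nSegments = object@nSegments, pulseShape = object@pulseShape,
    offsets = object@offsets, referenceOffsets = object@referenceOffsets),
    path)
  invisible(path)
}

#' @rdname writeSchemeYaml
#' @export
readSchemeYaml <- function(path) {
  y <- yaml::read_yaml(path)
  new("SaturationScheme", mode = y$mode, nPulses = y$nPulses,
      pulseDuration = y$pulseDuration, flipAngle = y$flipAngle,
      dutyCycle = y$dutyCycle, cwB1 = y$cwB1, nSegments = y$nSegments,
      pulseShape = y$pulseShape, offsets = as.numeric(y$offsets),
      referenceOffsets = as.numeric(y$referenceOffsets))
}

#' @rdname writeSchemeYaml
#' @export
writeSystemYaml <- function(object, path) {
  stopifnot(is(object, "SpinSystem"))
  yaml::write_yaml(list(
    larmorFrequency = object@larmorFrequency,
    pools = lapply(object@pools, function(p)
      list(name = p@name, offset = p@offset, rate = p@rate,
           fraction = p@fraction, t1 = p@t1, t2 = p@t2))), path)
  invisible(path)
}

#' @rdname writeSchemeYaml
#' @export
readSystemYaml <- function(path) {
  y <- yaml::read_yaml(path)
  pools <- lapply(y$pools, function(p)
    new("ExchangePool", name = p$name, offset = p$offset, rate = p$rate,
        fraction = p$fraction, t1 = p$t1, t2 = p$t2))
  new("SpinSystem", pools = pools, larmorFrequency = y$larmorFrequency)
}

#' Read a per-voxel Z-spectrum stack from NIfTI
#'
#' The volume's last dimension indexes saturation frames; a CSV sidecar with
#' columns `offset_ppm` and `is_reference` (0/1) declares the offset of each
#' frame and which frames are the far-off-resonance normalization scans.
#'
#' @param niftiPath NIfTI volume whose last dimension indexes frames.
#' @param sidecarPath sidecar CSV path.
#' @return list with `offsets` and `spectra` (one [ZSpectrum-class] per
#'   in-plane voxel, in column-major order).
#' @export
readNiftiStack <- function(niftiPath, sidecarPath) {
  vol <- RNifti::readNifti(niftiPath)
  arr <- as.array(vol)
  side <- read.csv(sidecarPath)
  if (!all(c("offset_ppm", "is_reference") %in% names(side)))
    stop("sidecar must have columns offset_ppm, is_reference")
  nf <- dim(arr)[length(dim(arr))]
  if (nrow(side) != nf)
    stop("sidecar rows (", nrow(side), ") do not match volume frames (",
         nf, ")")
  mat <- matrix(arr, ncol = nf)  # voxels x frames
  isRef <- side$is_reference != 0
  if (!any(isRef)) stop("sidecar declares no reference frames")
  offs <- side$offset_ppm[!isRef]
  spectra <- lapply(seq_len(nrow(mat)), function(v) {
    zSpectrum(offs, mat[v, !isRef], z0 = mean(mat[v, isRef]))
  })
  list(offsets = sort(offs), spectra = spectra)
}
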