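# shared fixtures: small spin systems and reduced saturation schemes

waterOnly <- function(t1 = 1.7, t2 = 0.14) {
  spinSystem(waterPool(t1, t2))
}

twoPool <- function(k = 1000, f = 5e-4, t1w = 1.7, t2w = 0.14) {
  spinSystem(waterPool(t1w, t2w),
             exchangePool("amine", 2.8, k, f, 1, 0.01))
}

threePool <- function(k = 1000, f = 5e-4, t1w = 1.7, t2w = 0.14,
                      kNoe = 20, fNoe = 2e-3) {
  spinSystem(waterPool(t1w, t2w),
             exchangePool("amine", 2.8, k, f, 1, 0.01),
             exchangePool("noe", -3.5, kNoe, fNoe, 1, 0.005))
}

# short train / sparse grid variants keep brute-force comparisons cheap
tinyScheme <- function(nPulses = 3, nSegments = 4,
                       offsets = c(-5, -2.8, 0, 2.8, 5)) {
  saturationScheme(nPulses = nPulses, nSegments = nSegments,
                   offsets = offsets)
}

randomSystem <- function(nPools = 2) {
  ps <- list(waterPool(runif(1, 0.3, 2.5), runif(1, 0.03, 0.2)))
  offs <- c(2.8, -3.5, 2.0)
  for (j in seq_len(nPools - 1)) {
    ps[[j + 1]] <- exchangePool(paste0("p", j), offs[j],
                                10^runif(1, 1, 3.5), 10^runif(1, -4, -2.5),
                                runif(1, 0.5, 1.5), runif(1, 0.004, 0.02))
  }
  do.call(spinSystem, ps)
}
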