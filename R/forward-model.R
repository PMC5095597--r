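# Bloch-McConnell forward model: generator assembly, exact propagation and
# Z-spectrum simulation under CW or pulsed Gaussian-train saturation.

GAMMA_RAD_PER_UT <- 2 * pi * 42.577  # proton, rad s^-1 per uT

#' Bloch-McConnell evolution generator
#'
#' Assembles the affine generator of the Bloch-McConnell equations for a
#' multi-pool spin system in the rotating frame of the saturation field:
#' relaxation, water-pool exchange with detailed balance (forward rate from
#' water to a pool equals `rate * fraction`), off-resonance precession at
#' `pool offset - saturation offset`, and B1 nutation. The state vector is
#' `(Mx, My, Mz)` per pool plus a trailing constant 1, so the generator is a
#' `(3n+1) x (3n+1)` matrix whose last row is zero.
#'
#' @param system a [SpinSystem-class].
#' @param b1 saturation amplitude in uT (>= 0).
#' @param offset saturation offset in ppm.
#' @return the square evolution generator matrix.
#' @examples
#' sys <- spinSystem(waterPool(1.7, 0.14))
#' G <- blochGenerator(sys, b1 = 0, offset = 0)
#' # z row encodes dMz/dt = (M0 - Mz)/T1
#' stopifnot(all.equal(G[3, 3], -1 / 1.7), all.equal(G[3, 4], 1 / 1.7))
#' @export
blochGenerator <- function(system, b1, offset) {
  stopifnot(is(system, "SpinSystem"))
  if (!is.finite(b1) || b1 < 0 || !is.finite(offset))
    stop("b1 must be finite and >= 0 and offset finite")
  P <- poolMatrix(system)
  if (!all(is.finite(P))) stop("non-finite pool parameters")
  .bmGeneratorCpp(P, system@larmorFrequency, b1, offset)
}

#' Equilibrium state of a spin system
#'
#' @param system a [SpinSystem-class].
#' @return state vector with `Mz = fraction` for each pool, transverse
#'   components zero, and the trailing affine constant 1.
#' @export
equilibriumState <- function(system) {
  P <- poolMatrix(system)
  n <- nrow(P)
  x <- numeric(3 * n + 1)
  x[3 * seq_len(n)] <- ifelse(seq_len(n) == 1, 1, P[, "fraction"])
  x[3 * n + 1] <- 1
  x
}

#' Propagate a state under a constant generator
#'
#' Exact piecewise-constant propagation by matrix exponential of the affine
#' system: `state(t) = expm(G t) state(0)`. Satisfies the composition property
#' `propagateState(G, a + b, x) = propagateState(G, b, propagateState(G, a, x))`.
#'
#' @param generator matrix from [blochGenerator()].
#' @param duration evolution time (s, >= 0).
#' @param state state vector (length `nrow(generator)`, last element 1).
#' @return the state after `duration`.
#' @export
propagateState <- function(generator, duration, state) {
  if (!is.finite(duration) || duration < 0) stop("duration must be >= 0")
  if (duration == 0) return(state)
  out <- as.vector(.expmGenCpp(generator, duration) %*% state)
  if (!all(is.finite(out))) stop("numerical overflow in propagation")
  out
}

#' Steady-state water signal under CW saturation
#'
#' Solves the linear fixed point of the affine Bloch-McConnell system
#' (`generator %*% state = 0` with the constant row) instead of time-stepping;
#' equals the infinite-duration limit of [propagateState()].
#'
#' @param system a [SpinSystem-class].
#' @param b1 CW amplitude (uT).
#' @param offsets saturation offsets (ppm).
#' @return water Mz/M0 at each offset.
#' @export
cwSteadyState <- function(system, b1, offsets) {
  as.vector(.zspecCwCpp(poolMatrix(system), system@larmorFrequency, b1,
                        offsets))
}

# per-segment B1 amplitudes (uT) of one shaped pulse, normalized so the
# discretized integral of gamma*B1 dt equals the flip angle
pulseSegments <- function(scheme) {
  ns <- as.integer(scheme@nSegments)
  if (ns < 1) stop("nSegments must be >= 1")
  tp <- scheme@pulseDuration
  dt <- tp / ns
  tm <- (seq_len(ns) - 0.5) * dt
  g <- switch(scheme@pulseShape,
    gaussian = {
      sigma <- tp / 6  # truncation at +-3 sigma
      exp(-(tm - tp / 2)^2 / (2 * sigma^2))
    },
    rect = rep(1, ns))
  flipRad <- scheme@flipAngle * pi / 180
  amp <- flipRad / (GAMMA_RAD_PER_UT * sum(g) * dt)
  list(b1 = amp * g, dt = dt,
       gap = tp * (1 / scheme@dutyCycle - 1))
}

#' Simulate a saturation pulse train at one offset
#'
#' Each pulse is discretized into `nSegments` piecewise-constant steps of a
#' truncated Gaussian (or rectangular) envelope scaled so the integrated
#' nutation equals the flip angle, followed by an RF-off gap set by the duty
#' cycle; the pattern repeats `nPulses` times starting from `initialState`.
#'
#' @param system a [SpinSystem-class].
#' @param scheme a [SaturationScheme-class] with `mode = "gaussian_train"`.
#' @param offset saturation offset (ppm).
#' @param initialState optional starting state (default thermal equilibrium).
#' @return water Mz/M0 after the train.
#' @export
simulatePulseTrain <- function(system, scheme, offset, initialState = NULL) {
  stopifnot(is(scheme, "SaturationScheme"))
  if (scheme@mode != "gaussian_train")
    stop("simulatePulseTrain requires mode = 'gaussian_train'")
  seg <- pulseSegments(scheme)
  P <- poolMatrix(system)
  if (is.null(initialState)) {
    as.vector(.zspecPulsedCpp(P, system@larmorFrequency, offset, seg$b1,
                              seg$dt, seg$gap, as.integer(scheme@nPulses)))
  } else {
    # generic-start path: compose the per-period propagator explicitly
    state <- initialState
    Gg <- blochGenerator(system, 0, offset)
    for (p in seq_len(scheme@nPulses)) {
      for (i in seq_along(seg$b1)) {
        G <- blochGenerator(system, seg$b1[i], offset)
        state <- propagateState(G, seg$dt, state)
      }
      if (seg$gap > 0) state <- propagateState(Gg, seg$gap, state)
    }
    state[3]
  }
}

#' Simulate a Z spectrum
#'
#' One simulation per offset, each starting from thermal equilibrium (the
#' long repetition time of the emulated acquisition guarantees full recovery
#' between offsets). The reference signal `z0` is the mean of the simulations
#' at the scheme's reference offsets. For `mode = "cw"` the steady-state
#' solution is used.
#'
#' @param system a [SpinSystem-class].
#' @param scheme a [SaturationScheme-class].
#' @return a [ZSpectrum-class] with raw signals and `z0` stored separately.
#' @export
simulateZSpectrum <- function(system, scheme) {
  stopifnot(is(system, "SpinSystem"), is(scheme, "SaturationScheme"))
  if (!length(scheme@offsets)) stop("scheme has no offsets")
  offs <- scheme@offsets
  refs <- scheme@referenceOffsets
  all <- c(offs, refs)
  z <- if (scheme@mode == "cw") {
    cwSteadyState(system, scheme@cwB1, all)
  } else {
    seg <- pulseSegments(scheme)
    as.vector(.zspecPulsedCpp(poolMatrix(system), system@larmorFrequency,
                              all, seg$b1, seg$dt, seg$gap,
                              as.integer(scheme@nPulses)))
  }
  n <- length(offs)
  zSpectrum(offs, z[seq_len(n)], z0 = mean(z[-seq_len(n)]))
}

#' CW-equivalent B1 of a pulse train
#'
#' Root-mean-square B1 over the full pulse + gap period (power equivalence).
#' For a CW scheme this is the CW amplitude itself.
#'
#' @param scheme a [SaturationScheme-class].
#' @return equivalent CW amplitude in uT.
#' @examples
#' cwEquivalentB1(saturationScheme())  # ~0.42 uT for the default train
#' @export
cwEquivalentB1 <- function(scheme) {
  if (scheme@mode == "cw") return(scheme@cwB1)
  seg <- pulseSegments(scheme)
  period <- scheme@pulseDuration + seg$gap
  sqrt(sum(seg$b1^2 * seg$dt) / period)
}
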