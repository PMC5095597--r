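# Independent numerical oracle: hand-written Bloch-McConnell derivative
# integrated with deSolve. Written directly from the physics (relaxation,
# detailed-balance exchange with water, off-resonance precession, B1
# nutation) without touching the package's generator assembly.

oracleDeriv <- function(t, y, pr) {
  P <- pr$P  # data.frame: offset, k, f, t1, t2 (water first)
  w1 <- 2 * pi * 42.577 * pr$b1
  n <- nrow(P)
  dy <- numeric(3 * n)
  for (i in seq_len(n)) {
    dw <- 2 * pi * pr$larmor * (P$offset[i] - pr$offsetRf)
    R1 <- 1 / P$t1[i]
    R2 <- 1 / P$t2[i]
    ix <- 3 * i - 2; iy <- 3 * i - 1; iz <- 3 * i
    M0 <- if (i == 1) 1 else P$f[i]
    dy[ix] <- -R2 * y[ix] + dw * y[iy]
    dy[iy] <- -dw * y[ix] - R2 * y[iy] + w1 * y[iz]
    dy[iz] <- -w1 * y[iy] - R1 * (y[iz] - M0)
  }
  if (n > 1) {
    for (i in 2:n) {
      kb <- P$k[i]          # pool -> water
      kf <- P$k[i] * P$f[i] # water -> pool (detailed balance)
      for (c in 0:2) {
        wi <- 1 + c; pi <- 3 * (i - 1) + 1 + c
        dy[wi] <- dy[wi] + kb * y[pi] - kf * y[wi]
        dy[pi] <- dy[pi] + kf * y[wi] - kb * y[pi]
      }
    }
  }
  list(dy)
}

oraclePoolFrame <- function(system) {
  do.call(rbind, lapply(pools(system), function(p)
    data.frame(offset = p@offset, k = p@rate, f = p@fraction,
               t1 = p@t1, t2 = p@t2)))
}

oracleEquilibrium <- function(system) {
  P <- oraclePoolFrame(system)
  y <- numeric(3 * nrow(P))
  y[3 * seq_len(nrow(P))] <- c(1, P$f[-1])
  y
}

# integrate the hand-written derivative for a constant-B1 interval
oracleEvolve <- function(system, b1, offsetRf, duration, y0 = NULL,
                         tol = 1e-12) {
  if (is.null(y0)) y0 <- oracleEquilibrium(system)
  pr <- list(P = oraclePoolFrame(system), b1 = b1,
             larmor = larmorFrequency(system), offsetRf = offsetRf)
  out <- deSolve::ode(y0, c(0, duration), oracleDeriv, pr, method = "lsoda",
                      rtol = tol, atol = tol, maxsteps = 1e6)
  as.numeric(out[2, -1])
}
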