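# Shared oracles and fixture builders. Oracles are deliberately independent
# of the implementation paths they check.

# numerical convolution of the hydrolysis-time density with an exponential
# release density (quadrature oracle for the delayed-release closed form)
convolvedDelayedPdf <- function(t, kCtp, kOff) {
  vapply(t, function(T) {
    if (T == 0) return(0)
    integrate(function(u)
      2 * kCtp * exp(-kCtp * u) * (1 - exp(-kCtp * u)) *
        kOff * exp(-kOff * (T - u)),
      0, T, rel.tol = 1e-12, abs.tol = 1e-14)$value
  }, 0)
}

# admissible random rate pairs away from the degeneracies kOff = kCtp, 2 kCtp
randomRatePairs <- function(n, seed = 99) {
  set.seed(seed)
  out <- list()
  while (length(out) < n) {
    a <- runif(1, 0.005, 0.1)
    b <- runif(1, 0.005, 0.3)
    if (abs(b - a) > 0.1 * a && abs(b - 2 * a) > 0.1 * a)
      out[[length(out) + 1]] <- c(kCtp = a, kOff = b)
  }
  out
}

# straight relaxed chain state (bonds at the equilibrium length)
straightChainState <- function(n) {
  b0 <- equilibriumBondLength()
  new("PolymerState", coords = cbind((seq_len(n) - 1) * b0, 0, 0),
      roles = rep("plain", n), anchors = as.integer(c(1, n)), time = 0)
}

# noiseless kymograph with Gaussian spots along a prescribed path (px)
spotKymograph <- function(path, npx = 60, amp = 200, sigmaPx = 1.2,
                          nmPerPixel = 110, secPerFrame = 0.1) {
  m <- matrix(0, length(path), npx)
  for (f in seq_along(path)) {
    px <- seq_len(npx)
    m[f, ] <- amp * exp(-(px - path[f])^2 / (2 * sigmaPx^2))
  }
  kymograph(list(ParB = m), nmPerPixel, secPerFrame)
}

# transition matrix of a blocked/reflecting lattice walk (oracle for
# diffusionUpdate): states are free beads only
latticeTransitionMatrix <- function(nBeads, roadblock, moveProb = 0.125) {
  P <- matrix(0, nBeads, nBeads)
  for (i in seq_len(nBeads)) {
    if (i == roadblock) next
    for (d in c(-1L, 1L)) {
      j <- i + d
      ok <- j >= 1 && j <= nBeads && j != roadblock
      if (ok) P[i, j] <- P[i, j] + moveProb / 2
      else P[i, i] <- P[i, i] + moveProb / 2
    }
    P[i, i] <- P[i, i] + 1 - moveProb
  }
  P
}
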