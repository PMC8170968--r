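# random SPD matrix with moderate conditioning
rand_spd <- function(d, scale = 1) {
  A <- matrix(rnorm(d * d), d)
  S <- crossprod(A) / d + diag(d) * 0.1
  S * scale
}

# closed-form geodesic midpoint of two SPD matrices under the
# affine-invariant metric: A^{1/2} (A^{-1/2} B A^{-1/2})^{1/2} A^{1/2}
geodesic_midpoint <- function(A, B) {
  ea <- eigen(A, symmetric = TRUE)
  Ah <- ea$vectors %*% (sqrt(ea$values) * t(ea$vectors))
  Aih <- ea$vectors %*% ((1 / sqrt(ea$values)) * t(ea$vectors))
  Mi <- Aih %*% B %*% Aih
  em <- eigen((Mi + t(Mi)) / 2, symmetric = TRUE)
  Mh <- em$vectors %*% (sqrt(em$values) * t(em$vectors))
  Ah %*% Mh %*% Ah
}

# small deterministic two-class trial list with a planted spatial
# variance contrast on channel 1 vs channel 2
toy_trials <- function(n_per_class = 6, C = 4, L = 60, seed = 42) {
  set.seed(seed)
  labels <- rep(c(1, -1), each = n_per_class)
  trials <- lapply(labels, function(y) {
    X <- matrix(rnorm(C * L), C, L)
    g <- if (y > 0) c(2, 0.5) else c(0.5, 2)
    X[1, ] <- X[1, ] * g[1]
    X[2, ] <- X[2, ] * g[2]
    X
  })
  list(trials = trials, labels = labels)
}

# single-sided periodogram band power of a vector (FFT oracle)
band_power <- function(x, fs, low, high) {
  n <- length(x)
  p <- abs(fft(x))^2 / n
  f <- (0:(n - 1)) * fs / n
  sum(p[f >= low & f <= high & f <= fs / 2]) / n
}
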