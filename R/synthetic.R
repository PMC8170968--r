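#' Configuration for the synthetic two-class EEG generator
#'
#' The generator emulates the structure sensorimotor-rhythm decoding relies
#' on: narrowband oscillatory sources whose power is attenuated or enhanced
#' depending on the imagined task (ERD-like modulation), mixed into the
#' channels through a fixed spatial mixing matrix together with spatially
#' correlated broadband noise. The two classes then differ in their spatial
#' covariance within the signal band, which is exactly what CSP-type
#' pipelines exploit.
#'
#' @param n_trials_per_class trials per class (>= 2).
#' @param n_channels number of channels C (>= 2).
#' @param fs sampling rate in Hz; must exceed twice the upper band edge.
#' @param duration_s trial length in seconds.
#' @param signal_band numeric length-2, oscillation band in Hz
#'   (default `c(10, 13)`, the upper mu band).
#' @param snr linear ratio of discriminative-source variance to per-channel
#'   noise variance; also sets the class separation (see Details). `snr = 0`
#'   yields two identical class distributions.
#' @param n_sources number of discriminative sources (default 2).
#' @param seed integer seed; the same seed gives bit-identical output.
#' @details Class separation is parameterised by a modulation depth
#'   `delta = (sqrt(1+snr) - 1)/(sqrt(1+snr) + 1)`, chosen so the ratio of
#'   the class band-power variances at a modulated source equals
#'   `((1+delta)/(1-delta))^2 = 1 + snr`. Odd-numbered sources are boosted
#'   for class +1 and attenuated for class -1; even-numbered sources are
#'   modulated oppositely.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_trials_per_class, n_channels, fs, duration_s,
                       signal_band = c(10, 13), snr = 1,
                       n_sources = 2, seed = 1) {
  if (n_trials_per_class < 2) stop("n_trials_per_class must be >= 2")
  if (n_channels < 2) stop("n_channels must be >= 2")
  if (length(signal_band) != 2L || signal_band[1] <= 0 ||
      signal_band[2] <= signal_band[1])
    stop("signal_band must be (low, high) with 0 < low < high")
  if (fs <= 2 * signal_band[2])
    stop("fs must exceed twice the upper band edge")
  if (duration_s <= 0 || abs(duration_s * fs - round(duration_s * fs)) > 1e-9)
    stop("duration_s * fs must be a positive integer sample count")
  if (snr < 0) stop("snr must be >= 0")
  if (n_sources < 1 || n_sources > n_channels)
    stop("n_sources must be in [1, n_channels]")
  structure(list(n_trials_per_class = as.integer(n_trials_per_class),
                 n_channels = as.integer(n_channels), fs = fs,
                 duration_s = duration_s, signal_band = signal_band,
                 snr = snr, n_sources = as.integer(n_sources),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Evaluate an expression under a fixed seed
#'
#' Runs `expr` with the RNG seeded to `seed`, restoring the caller's RNG
#' state afterwards, so seeded steps do not perturb the surrounding
#' random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

delta_from_snr <- function(snr) {
  s <- sqrt(1 + snr)
  (s - 1) / (s + 1)
}

# unit-variance sinusoid at frequency f (Hz) with phase phi
narrowband_wave <- function(f, phi, n, fs) {
  sqrt(2) * sin(2 * pi * f * (0:(n - 1)) / fs + phi)
}

# core generator; class_freqs overrides the per-trial random frequency with a
# fixed per-class frequency (used to plant purely spectral discrimination)
simulate_trials <- function(cfg, delta, class_freqs = NULL,
                            shuffle_labels = FALSE) {
  with_seed(cfg$seed, {
    C <- cfg$n_channels
    T_ <- as.integer(round(cfg$duration_s * cfg$fs))
    n <- cfg$n_trials_per_class
    A <- qr.Q(qr(matrix(stats::rnorm(C * C), C, C)))
    amp <- sqrt(cfg$snr)
    labels <- rep(c(1, -1), each = n)
    data <- array(NA_real_, c(2 * n, C, T_))
    for (i in seq_len(2 * n)) {
      y <- labels[i]
      X <- A %*% matrix(stats::rnorm(C * T_), C, T_)
      for (k in seq_len(cfg$n_sources)) {
        f <- if (is.null(class_freqs))
          stats::runif(1, cfg$signal_band[1], cfg$signal_band[2])
        else if (y > 0) class_freqs[1] else class_freqs[2]
        phi <- stats::runif(1, 0, 2 * pi)
        sgn <- if (k %% 2 == 1) 1 else -1          # opposite modulation
        a_k <- amp * (1 + sgn * y * delta)
        X <- X + a_k * A[, k] %o% narrowband_wave(f, phi, T_, cfg$fs)
      }
      data[i, , ] <- X
    }
    if (shuffle_labels) labels <- sample(labels)
    ts <- trial_set(data, labels, cfg$fs)
    attr(ts, "mixing") <- A
    attr(ts, "delta") <- delta
    attr(ts, "seed") <- cfg$seed
    ts
  })
}

#' Generate a two-class synthetic EEG trial set
#'
#' Draws a fixed random orthonormal mixing matrix, adds spatially mixed
#' broadband Gaussian noise, and superimposes narrowband oscillations
#' (random frequency within `signal_band` and random phase per trial) on
#' fixed spatial patterns, with class-dependent amplitude modulation as
#' described in [sim_config()]. The mixing matrix is attached as attribute
#' `"mixing"` and the modulation depth as `"delta"` so tests can verify the
#' planted structure directly.
#'
#' @param cfg a [sim_config()].
#' @return a `trial_set` with balanced +1 / -1 labels (class +1 first).
#' @export
generate_trials <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  simulate_trials(cfg, delta_from_snr(cfg$snr))
}

#' Generate label-free null data
#'
#' Both classes are drawn from the identical generative process (no
#' class-dependent modulation) and labels are assigned by random
#' permutation, so any classifier's expected accuracy is chance.
#'
#' @param cfg a [sim_config()].
#' @return a `trial_set`.
#' @export
generate_null_trials <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  simulate_trials(cfg, 0, shuffle_labels = TRUE)
}

#' Generate trials whose class difference is purely spectral
#'
#' Both classes share the same spatial patterns and the same oscillation
#' amplitude; they differ only in oscillation frequency (`f_pos` for class
#' +1, `f_neg` for class -1). Plain CSP sees identical spatial covariances,
#' but a delay-embedded (CSSP) representation resolves the frequency
#' difference, and does so best at delays where the two frequencies
#' dephase most — this plants a preferred temporal delay that
#' [select_tau()] should recover.
#'
#' @param cfg a [sim_config()]; `signal_band` is ignored in favour of the
#'   explicit class frequencies.
#' @param f_pos,f_neg oscillation frequency (Hz) of class +1 / class -1.
#' @return a `trial_set`.
#' @export
generate_lag_trials <- function(cfg, f_pos, f_neg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (f_pos <= 0 || f_neg <= 0 || f_pos >= cfg$fs / 2 || f_neg >= cfg$fs / 2)
    stop("class frequencies must lie in (0, fs/2)")
  simulate_trials(cfg, 0, class_freqs = c(f_pos, f_neg))
}

#' Delay at which two oscillation frequencies dephase most
#'
#' For a delay-embedded channel pair the sensitivity to an oscillation at
#' frequency f varies as cos(2*pi*f*tau/fs); the delay separating two
#' frequencies best is the grid value maximising the absolute difference of
#' these cosines. Used to define the planted delay for recovery tests.
#'
#' @param f_pos,f_neg the two class frequencies in Hz.
#' @param fs sampling rate in Hz.
#' @param tau_grid candidate integer delays (samples).
#' @return the grid delay with maximal dephasing (smallest on ties).
#' @export
planted_tau <- function(f_pos, f_neg, fs, tau_grid) {
  d <- abs(cos(2 * pi * f_pos * tau_grid / fs) -
           cos(2 * pi * f_neg * tau_grid / fs))
  tau_grid[which.max(d)]
}

#' Generate a continuous record with cue times
#'
#' Concatenates generated trials separated by pure-noise gaps, returning
#' the continuous multichannel record plus 0-based cue sample indices, to
#' exercise cue-relative epoch extraction.
#'
#' @param cfg a [sim_config()].
#' @param gap_s seconds of noise between consecutive trials (default 1).
#' @return list with `record` (C x N matrix), `fs`, `cues` (0-based sample
#'   index of each trial onset), and `labels`.
#' @export
generate_continuous <- function(cfg, gap_s = 1) {
  ts <- generate_trials(cfg)
  A <- attr(ts, "mixing")
  C <- cfg$n_channels
  T_ <- dim(ts$data)[3]
  gap <- as.integer(round(gap_s * cfg$fs))
  n <- n_trials(ts)
  N <- n * T_ + (n + 1) * gap
  noise <- with_seed(cfg$seed + 1L, A %*% matrix(stats::rnorm(C * N), C, N))
  record <- noise
  cues <- integer(n)
  pos <- gap                                     # 0-based onset of trial 1
  for (i in seq_len(n)) {
    record[, (pos + 1):(pos + T_)] <- record[, (pos + 1):(pos + T_)] +
      trial_matrix(ts, i)
    cues[i] <- pos
    pos <- pos + T_ + gap
  }
  list(record = record, fs = cfg$fs, cues = cues, labels = ts$labels)
}
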