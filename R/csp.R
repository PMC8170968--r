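#' Temporally delayed windows of an epoch
#'
#' Splits a `C x T` epoch into `n` windows of common length
#' `L = T - (n-1)*tau`, the i-th starting at offset `(i-1)*tau` samples.
#' With `n = 1` the whole epoch is returned; with `tau = 0` the windows are
#' identical copies.
#'
#' @param x `C x T` numeric matrix.
#' @param n number of windows (>= 1).
#' @param tau integer delay between consecutive windows, in samples (>= 0).
#' @return list of `n` matrices `C x L`.
#' @export
make_windows <- function(x, n, tau) {
  x <- as.matrix(x)
  if (n < 1 || tau < 0) stop("need n >= 1 and tau >= 0")
  L <- ncol(x) - (n - 1) * tau
  if (L <= 0)
    stop(sprintf("window length %d - (%d-1)*%d <= 0", ncol(x), n, tau))
  lapply(seq_len(n), function(i) {
    off <- (i - 1) * tau
    x[, (off + 1):(off + L), drop = FALSE]
  })
}

#' Delay-embedded (CSSP) channel-augmented window pairs
#'
#' For every pair `i < j` of the input windows, stacks the delayed window
#' under the earlier one as extra channels, yielding a `2C x L` matrix.
#' CSP on such a stack can realise frequency-selective (spatio-spectral)
#' filters. `n` windows yield `n(n-1)/2` augmented pairs, ordered
#' `(1,2), (1,3), ..., (2,3), ...`.
#'
#' @param windows list of equally shaped `C x L` matrices.
#' @return named list of `2C x L` matrices; empty when fewer than 2 windows.
#' @export
make_cssp_windows <- function(windows) {
  n <- length(windows)
  if (n < 2) return(list())
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      out[[paste0("cssp_", i, "_", j)]] <- rbind(windows[[i]], windows[[j]])
    }
  }
  out
}

#' Enumerate the CSP-TSM / CSSP-TSM processes for n windows
#'
#' @param n number of windows.
#' @return data.frame with columns `kind` ("CSP-TSM" or "CSSP-TSM"),
#'   `window_i`, `window_j` (NA for plain windows), in pipeline order:
#'   the n plain windows first, then the delay-embedded pairs.
#' @export
spectra_processes <- function(n) {
  plain <- data.frame(kind = rep("CSP-TSM", n), window_i = seq_len(n),
                      window_j = NA_integer_)
  if (n < 2) return(plain)
  pairs <- do.call(rbind, lapply(seq_len(n - 1), function(i)
    data.frame(kind = "CSSP-TSM", window_i = i, window_j = (i + 1):n)))
  rbind(plain, pairs)
}

# ensure positive definiteness: add eps*tr/d*I when nearly singular
regularize_cov <- function(S, eps = 1e-9) {
  d <- nrow(S)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  tr <- sum(diag(S))
  if (min(ev) < 1e-12 * tr) S <- S + (eps * tr / d) * diag(d)
  S
}

# deterministic sign: first component of magnitude > tol positive
fix_signs <- function(W, tol = 1e-10) {
  for (k in seq_len(ncol(W))) {
    nz <- which(abs(W[, k]) > tol)
    if (length(nz) && W[nz[1], k] < 0) W[, k] <- -W[, k]
  }
  W
}

#' Learn common spatial pattern filters
#'
#' Per-trial spatial covariances `X X' / tr(X X')` are averaged per class;
#' the generalized eigenproblem `Cp w = lambda (Cp + Cn) w` is solved by
#' whitening the composite covariance, and the `m` eigenvectors of largest
#' eigenvalue followed by the `m` of smallest are retained. The resulting
#' filters maximise the variance ratio between classes in both directions
#' and satisfy `W' (Cp + Cn) W = I`.
#'
#' @param trials list of `C x L` matrices (all the same channel count).
#' @param labels numeric vector of +1 / -1, one per trial.
#' @param m number of filter pairs to keep (2m filters; default 3).
#' @return object of class `spatial_filter_bank` with elements `W`
#'   (`C x 2m`), `eigvals` (the 2m retained generalized eigenvalues, in
#'   descending order), `m`, and `channels_in`.
#' @export
learn_csp <- function(trials, labels, m = 3) {
  if (length(trials) != length(labels))
    stop("one label per trial required")
  if (length(unique(labels)) < 2)
    stop("both classes must be present to learn CSP filters")
  C <- nrow(trials[[1]])
  if (2 * m > C) stop("2m filters exceed channel count")
  covs <- lapply(trials, function(X) {
    if (any(!is.finite(X))) stop("non-finite trial data")
    S <- tcrossprod(X)
    tr <- sum(diag(S))
    if (tr <= 0) stop("zero-power trial")
    S / tr
  })
  Cp <- Reduce(`+`, covs[labels > 0]) / sum(labels > 0)
  Cn <- Reduce(`+`, covs[labels < 0]) / sum(labels < 0)
  M <- Cp + Cn
  em <- eigen(M, symmetric = TRUE)
  # whiten on the principal subspace only: referencing (e.g. CAR) and
  # delay-embedded channel stacks make M rank deficient, and whitening a
  # null direction would manufacture filters with no signal content
  keep <- em$values > 1e-8 * em$values[1]
  rank <- sum(keep)
  if (2 * m > rank)
    stop(sprintf("composite covariance rank %d supports at most %d filters",
                 rank, 2 * (rank %/% 2)))
  Minvhalf <- em$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(em$values[keep]), rank)       # C x rank
  S <- crossprod(Minvhalf, Cp %*% Minvhalf)
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)          # eigenvalues descending
  sel <- c(seq_len(m), (rank - m + 1):rank)
  W <- fix_signs(Minvhalf %*% es$vectors[, sel, drop = FALSE])
  structure(list(W = W, eigvals = es$values[sel], m = m, channels_in = C),
            class = "spatial_filter_bank")
}

#' Apply spatial filters to a trial
#'
#' @param bank a `spatial_filter_bank` from [learn_csp()].
#' @param X `C x L` matrix with `C` equal to the bank's input channels.
#' @return filtered signal `Z = W' X`, a `2m x L` matrix.
#' @export
apply_filters <- function(bank, X) {
  stopifnot(inherits(bank, "spatial_filter_bank"))
  X <- as.matrix(X)
  if (nrow(X) != bank$channels_in)
    stop(sprintf("trial has %d channels, filter bank expects %d",
                 nrow(X), bank$channels_in))
  crossprod(bank$W, X)
}

#' Log-variance CSP features
#'
#' The k-th feature is `log(var(Z_k) / sum_j var(Z_j))` over the filtered
#' rows, so `sum_k exp(f_k) = 1` and the features are invariant to overall
#' scaling of the trial. Variances use the `L - 1` denominator.
#'
#' @param Z `2m x L` filtered trial.
#' @return numeric vector of `2m` features.
#' @export
csp_features <- function(Z) {
  Z <- as.matrix(Z)
  if (ncol(Z) < 2) stop("need at least 2 samples for a variance")
  v <- apply(Z, 1, stats::var)
  if (any(v <= 0)) stop("zero-variance filtered row; cannot form features")
  log(v / sum(v))
}
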