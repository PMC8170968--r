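# Symmetric-eigendecomposition matrix functions with an eigenvalue floor.
# All SPD geometry below goes through these.
sym_mat_fun <- function(M, f, floor = 1e-12) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  out <- e$vectors %*% (f(vals) * t(e$vectors))
  (out + t(out)) / 2
}
spd_sqrt    <- function(M) sym_mat_fun(M, sqrt)
spd_invsqrt <- function(M) sym_mat_fun(M, function(v) 1 / sqrt(v))
spd_logm    <- function(M) sym_mat_fun(M, log)
sym_expm    <- function(M) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  out <- e$vectors %*% (exp(e$values) * t(e$vectors))
  (out + t(out)) / 2
}

check_spd <- function(M, name = "matrix", tol = 1e-10) {
  if (!is.matrix(M) || nrow(M) != ncol(M))
    stop(name, " must be square")
  if (max(abs(M - t(M))) > tol * max(1, max(abs(M))))
    stop(name, " is not symmetric")
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop(name, " is not positive definite")
  invisible(TRUE)
}

as_spd <- function(x) {
  if (inherits(x, "riemannian_mean")) x$sigma else as.matrix(x)
}

#' Trace-normalized trial covariance
#'
#' `Sigma = Z Z' / tr(Z Z')`, the normalized spatial covariance of a
#' (filtered) trial; unit trace makes it invariant to overall signal
#' scale. A ridge of `1e-9 * tr/d` is added when the matrix is numerically
#' singular (e.g. duplicated channels from a zero-delay stack).
#'
#' @param Z `d x L` matrix.
#' @return `d x d` SPD matrix with trace 1 (before any ridge).
#' @export
trial_covariance <- function(Z) {
  Z <- as.matrix(Z)
  S <- tcrossprod(Z)
  tr <- sum(diag(S))
  if (tr <= 0) stop("all-zero trial: covariance undefined")
  regularize_cov(S / tr)
}

#' Riemannian (Karcher) mean of SPD matrices
#'
#' The point minimising the sum of squared affine-invariant distances to
#' the inputs, computed by the standard fixed-point iteration
#' `Sigma <- Sigma^{1/2} exp(mean_i log(Sigma^{-1/2} Sigma_i Sigma^{-1/2}))
#' Sigma^{1/2}`, initialised at the arithmetic mean and stopped when the
#' Frobenius norm of the mean log (the Riemannian gradient) drops below
#' `tol`.
#'
#' @param Sigmas list of SPD matrices of equal dimension.
#' @param tol convergence tolerance on the gradient norm (default 1e-8).
#' @param max_iter maximum fixed-point iterations (default 50).
#' @return object of class `riemannian_mean` with elements `sigma`,
#'   `iterations_used`, `final_gradient_norm`, `converged`.
#' @export
riemannian_mean <- function(Sigmas, tol = 1e-8, max_iter = 50) {
  if (length(Sigmas) < 1) stop("need at least one matrix")
  for (S in Sigmas) check_spd(S, "input covariance")
  Sigma <- Reduce(`+`, Sigmas) / length(Sigmas)
  gnorm <- Inf
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    Sh <- spd_sqrt(Sigma)
    Sih <- spd_invsqrt(Sigma)
    Mlog <- matrix(0, nrow(Sigma), ncol(Sigma))
    for (S in Sigmas) Mlog <- Mlog + spd_logm(Sih %*% S %*% Sih)
    Mlog <- Mlog / length(Sigmas)
    gnorm <- sqrt(sum(Mlog^2))
    if (gnorm <= tol) break
    Sigma <- Sh %*% sym_expm(Mlog) %*% Sh
    Sigma <- (Sigma + t(Sigma)) / 2
  }
  converged <- gnorm <= tol
  if (!converged)
    warning(sprintf("Karcher mean did not reach tol=%.1e in %d iterations (gradient %.2e)",
                    tol, max_iter, gnorm))
  structure(list(sigma = Sigma, iterations_used = iters,
                 final_gradient_norm = gnorm, converged = converged),
            class = "riemannian_mean")
}

#' Logarithmic map on the SPD manifold
#'
#' `Log_Sigma(Sigma_i) = Sigma^{1/2} log(Sigma^{-1/2} Sigma_i Sigma^{-1/2})
#' Sigma^{1/2}`: the tangent vector at `Sigma` pointing to `Sigma_i` under
#' the affine-invariant metric. Zero when the two matrices coincide.
#'
#' @param Sigma reference SPD matrix (or a `riemannian_mean`).
#' @param Sigma_i target SPD matrix.
#' @return symmetric matrix of the same dimension.
#' @export
log_map <- function(Sigma, Sigma_i) {
  S <- as_spd(Sigma); Si <- as_spd(Sigma_i)
  check_spd(S, "Sigma"); check_spd(Si, "Sigma_i")
  Sh <- spd_sqrt(S); Sih <- spd_invsqrt(S)
  out <- Sh %*% spd_logm(Sih %*% Si %*% Sih) %*% Sh
  (out + t(out)) / 2
}

# row-major upper-triangle (diagonal included) with off-diagonal * sqrt(2);
# preserves the Frobenius norm of a symmetric matrix
upper_vec <- function(M) {
  d <- nrow(M)
  out <- numeric(d * (d + 1) / 2)
  pos <- 1L
  for (i in seq_len(d)) {
    out[pos] <- M[i, i]
    pos <- pos + 1L
    if (i < d) {
      k <- d - i
      out[pos:(pos + k - 1L)] <- sqrt(2) * M[i, (i + 1):d]
      pos <- pos + k
    }
  }
  out
}

#' Tangent-space feature vector of a trial covariance
#'
#' Vectorizes `Sigma^{-1/2} Log_Sigma(Sigma_i) Sigma^{-1/2}` (equivalently
#' `log(Sigma^{-1/2} Sigma_i Sigma^{-1/2})`) by its row-major upper
#' triangle, diagonal included, with off-diagonal entries scaled by
#' `sqrt(2)`. The Euclidean norm of the result equals the affine-invariant
#' distance between `Sigma` and `Sigma_i`, so Euclidean classifiers in the
#' tangent space respect the manifold geometry locally.
#'
#' @param Sigma the reference point, normally the Riemannian mean of the
#'   training covariances (a `riemannian_mean` or SPD matrix).
#' @param Sigma_i SPD trial covariance.
#' @return numeric vector of length `d(d+1)/2` (21 for `d = 6`).
#' @export
tangent_vector <- function(Sigma, Sigma_i) {
  S <- as_spd(Sigma); Si <- as_spd(Sigma_i)
  check_spd(S, "Sigma"); check_spd(Si, "Sigma_i")
  Sih <- spd_invsqrt(S)
  upper_vec(spd_logm(Sih %*% Si %*% Sih))
}

#' Affine-invariant Riemannian distance between SPD matrices
#'
#' `sqrt(sum_k log^2 lambda_k)` where `lambda_k` are the eigenvalues of
#' `Sigma^{-1/2} Sigma_i Sigma^{-1/2}`. Symmetric, zero iff equal, and
#' invariant under congruence `Sigma -> G Sigma G'`.
#'
#' @param Sigma,Sigma_i SPD matrices (or `riemannian_mean` objects).
#' @return nonnegative scalar.
#' @export
riemannian_distance <- function(Sigma, Sigma_i) {
  S <- as_spd(Sigma); Si <- as_spd(Sigma_i)
  check_spd(S, "Sigma"); check_spd(Si, "Sigma_i")
  Sih <- spd_invsqrt(S)
  P <- Sih %*% Si %*% Sih
  ev <- eigen((P + t(P)) / 2, symmetric = TRUE, only.values = TRUE)$values
  sqrt(sum(log(pmax(ev, 1e-300))^2))
}
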