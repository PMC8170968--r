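test_that("delayed windows have the stated offsets and common length", {
  x <- matrix(seq_len(3 * 200), 3, byrow = TRUE)
  w <- make_windows(x, 3, 10)
  expect_length(w, 3)
  expect_true(all(vapply(w, ncol, integer(1)) == 180))
  expect_equal(w[[1]], x[, 1:180])
  expect_equal(w[[2]], x[, 11:190])
  expect_equal(w[[3]], x[, 21:200])
  expect_equal(make_windows(x, 1, 50)[[1]], x)       # n = 1: whole epoch
  w0 <- make_windows(x, 3, 0)                        # tau = 0: copies
  expect_equal(w0[[1]], w0[[3]])
  expect_error(make_windows(x, 3, 100), "<= 0")
})

test_that("delay-embedded pairs enumerate all window combinations", {
  x <- matrix(rnorm(10 * 100), 10)
  w3 <- make_windows(x, 3, 5)
  cs <- make_cssp_windows(w3)
  expect_length(cs, 3)                               # n(n-1)/2 for n = 3
  expect_named(cs, c("cssp_1_2", "cssp_1_3", "cssp_2_3"))
  expect_true(all(vapply(cs, nrow, integer(1)) == 20))
  expect_equal(cs[[1]], rbind(w3[[1]], w3[[2]]))
  expect_length(make_cssp_windows(make_windows(x, 2, 5)), 1)
  expect_length(make_cssp_windows(make_windows(x, 1, 5)), 0)
})

test_that("process enumeration is plain windows first, then pairs", {
  p <- spectra_processes(3)
  expect_equal(nrow(p), 6)
  expect_equal(p$kind, c(rep("CSP-TSM", 3), rep("CSSP-TSM", 3)))
  expect_equal(p$window_j[4:6], c(2L, 3L, 3L))
  expect_equal(nrow(spectra_processes(1)), 1)
})

test_that("CSP solves the 2x2 analytic instance", {
  # class covariances diag(2,1) and diag(1,2) after trace normalization
  trials <- list(diag(c(sqrt(2), 1)), diag(c(1, sqrt(2))))
  bank <- learn_csp(trials, c(1, -1), m = 1)
  expect_equal(bank$eigvals, c(2 / 3, 1 / 3), tolerance = 1e-10)
  # filters are the coordinate axes (up to scale, sign fixed positive)
  W <- apply(bank$W, 2, function(w) abs(w) / max(abs(w)))
  expect_equal(W, cbind(c(1, 0), c(0, 1)), tolerance = 1e-8)
})

test_that("identical class covariances give eigenvalues 1/2", {
  X <- matrix(rnorm(4 * 50), 4)
  bank <- learn_csp(list(X, X), c(1, -1), m = 2)
  expect_equal(bank$eigvals, rep(0.5, 4), tolerance = 1e-10)
})

test_that("learned filters satisfy the CSP invariants", {
  set.seed(3)
  toy <- toy_trials()
  bank <- learn_csp(toy$trials, toy$labels, m = 2)
  covs <- lapply(toy$trials, function(X) {
    S <- tcrossprod(X); S / sum(diag(S))
  })
  Cp <- Reduce(`+`, covs[toy$labels > 0]) / sum(toy$labels > 0)
  Cn <- Reduce(`+`, covs[toy$labels < 0]) / sum(toy$labels < 0)
  W <- bank$W
  expect_equal(crossprod(W, (Cp + Cn) %*% W), diag(4), tolerance = 1e-8)
  D <- crossprod(W, Cp %*% W)
  expect_lt(max(abs(D - diag(diag(D)))), 1e-8)    # simultaneous diagonalization
  expect_equal(diag(D), bank$eigvals, tolerance = 1e-8)

  # label swap reverses the eigenvalue spectrum
  bank2 <- learn_csp(toy$trials, -toy$labels, m = 2)
  expect_equal(bank2$eigvals, rev(1 - bank$eigvals), tolerance = 1e-8)

  expect_error(learn_csp(toy$trials, rep(1, 12), m = 2), "both classes")
})

test_that("the top filter dominates random directions in class-variance ratio", {
  set.seed(9)
  toy <- toy_trials(n_per_class = 8, C = 5, L = 80, seed = 10)
  covs <- lapply(toy$trials, function(X) {
    S <- tcrossprod(X); S / sum(diag(S))
  })
  Cp <- Reduce(`+`, covs[toy$labels > 0]) / 8
  Cn <- Reduce(`+`, covs[toy$labels < 0]) / 8
  bank <- learn_csp(toy$trials, toy$labels, m = 1)
  w1 <- bank$W[, 1]
  ratio <- function(w) drop(crossprod(w, Cp %*% w) / crossprod(w, Cn %*% w))
  dirs <- matrix(rnorm(5 * 10000), 5)
  rand_best <- max(apply(dirs, 2, ratio))
  expect_gte(ratio(w1) + 1e-10, rand_best)
})

test_that("filter application is the plain matrix product", {
  W <- matrix(c(1, 0, 0, 0, 1, 0), 3, 2)
  bank <- structure(list(W = W, eigvals = c(0.6, 0.4), m = 1, channels_in = 3),
                    class = "spatial_filter_bank")
  X <- matrix(seq_len(15), 3, 5)
  expect_equal(apply_filters(bank, X), X[1:2, ])      # row selection
  expect_equal(apply_filters(bank, matrix(0, 3, 5)), matrix(0, 2, 5))
  expect_equal(apply_filters(bank, X), crossprod(W, X))
  expect_error(apply_filters(bank, matrix(1, 4, 5)), "channels")
})

test_that("log-variance features are normalized and scale invariant", {
  set.seed(4)
  # rows with variances exactly 1..6
  Z <- t(sapply(1:6, function(k) {
    z <- rnorm(100); z <- (z - mean(z)) / sd(z) * sqrt(k); z
  }))
  f <- csp_features(Z)
  expect_equal(f, log((1:6) / 21), tolerance = 1e-10)
  expect_equal(sum(exp(f)), 1)
  expect_equal(csp_features(3.7 * Z), f, tolerance = 1e-10)
  Zeq <- matrix(rnorm(6 * 50), 6)
  Zeq <- Zeq / apply(Zeq, 1, sd)
  expect_equal(csp_features(Zeq), rep(log(1 / 6), 6), tolerance = 1e-10)
  expect_error(csp_features(rbind(rnorm(10), rep(1, 10))), "zero-variance")
})

test_that("zero-delay channel duplication is handled by the rank guard", {
  toy <- toy_trials(C = 5)
  stacks <- lapply(toy$trials, function(x) {
    w <- make_windows(x, 2, 0)
    make_cssp_windows(w)[[1]]
  })
  bank <- learn_csp(stacks, toy$labels, m = 2)       # rank 5, not 10
  bank_plain <- learn_csp(toy$trials, toy$labels, m = 2)
  expect_equal(bank$eigvals, bank_plain$eigvals, tolerance = 1e-6)
})
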