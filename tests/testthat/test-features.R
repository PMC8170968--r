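test_that("one process yields 27 features: 6 CSP then 21 TSM", {
  toy <- toy_trials(n_per_class = 6, C = 8, L = 120)
  proc <- spectra_processes(3)[1, ]
  model <- fit_process(toy$trials, toy$labels, proc, n_windows = 3,
                       tau = 5, m = 3)
  F1 <- transform_process(model, toy$trials)
  expect_equal(dim(F1), c(12, 27))
  expect_true(all(is.finite(F1)))
  # CSP block: each row's exp sums to 1
  expect_equal(rowSums(exp(F1[, 1:6])), rep(1, 12), tolerance = 1e-10)
})

test_that("a CSSP process consumes a 2C-channel stack", {
  toy <- toy_trials(n_per_class = 6, C = 8, L = 120)
  proc <- spectra_processes(3)[4, ]          # first window pair
  model <- fit_process(toy$trials, toy$labels, proc, 3, 5, m = 3)
  expect_equal(model$bank$channels_in, 16)
  expect_equal(ncol(transform_process(model, toy$trials)), 27)
})

test_that("refitting on identical data is deterministic", {
  toy <- toy_trials(n_per_class = 5, C = 8, L = 100)
  a <- assemble_features(toy$trials, toy$labels, 3, 5, m = 3)
  b <- assemble_features(toy$trials, toy$labels, 3, 5, m = 3)
  expect_identical(a$values, b$values)
})

test_that("assembly counts follow (n + n(n-1)/2) * 27", {
  toy <- toy_trials(n_per_class = 5, C = 8, L = 120)
  fm3 <- assemble_features(toy$trials, toy$labels, 3, 5, m = 3)
  expect_equal(ncol(fm3$values), 162)
  expect_equal(nrow(fm3$columns), 162)
  fm1 <- assemble_features(toy$trials, toy$labels, 1, 5, m = 3)
  expect_equal(ncol(fm1$values), 27)
  fm2 <- assemble_features(toy$trials, toy$labels, 2, 5, m = 3)
  expect_equal(ncol(fm2$values), 81)
  # fixed process order: plain windows 1..n, then pairs (1,2),(1,3),(2,3)
  expect_equal(unique(fm3$columns$process),
               c("CSP-TSM(w1)", "CSP-TSM(w2)", "CSP-TSM(w3)",
                 "CSSP-TSM(w1,w2)", "CSSP-TSM(w1,w3)", "CSSP-TSM(w2,w3)"))
})

test_that("column metadata round-trips every selected index", {
  toy <- toy_trials(n_per_class = 5, C = 8, L = 120)
  fm <- assemble_features(toy$trials, toy$labels, 3, 5, m = 3)
  tab <- f_score_table(fm$values, toy$labels)
  sel <- select_top_r(tab, 10)
  meta <- fm$columns[sel, ]
  expect_equal(nrow(meta), 10)
  expect_true(all(meta$kind %in% c("CSP", "TSM")))
  # each (process, kind, local) triple addresses exactly one column
  key <- paste(fm$columns$process, fm$columns$kind, fm$columns$local)
  expect_false(any(duplicated(key)))
  expect_equal(match(paste(meta$process, meta$kind, meta$local), key), sel)
})

test_that("Fisher score matches hand-computed values", {
  x <- c(1, 2, 3, 4, 5, 6)
  labels <- c(1, 1, 1, -1, -1, -1)
  expect_equal(f_score(x, labels), 2.25)     # (1.5^2 + 1.5^2) / (1 + 1)
  # identical class distributions score zero
  expect_equal(f_score(c(1, 2, 3, 1, 2, 3), labels), 0)
})

test_that("Fisher score scales quadratically with separation and is affine invariant", {
  labels <- rep(c(1, -1), each = 4)
  set.seed(3)
  base <- rnorm(4, sd = 0.5)
  x1 <- c(base + 1, base - 1)                # class-mean separation 2
  x2 <- c(base + 2, base - 2)                # class-mean separation 4
  # within-class variances are identical, so doubling the separation
  # quadruples the score (quadratic numerator)
  expect_equal(f_score(x2, labels), 4 * f_score(x1, labels),
               tolerance = 1e-10)
  # affine transform leaves the score unchanged
  expect_equal(f_score(3 * x1 - 7, labels), f_score(x1, labels),
               tolerance = 1e-10)
  expect_error(f_score(c(1, 2), c(1, -1)), ">= 2 samples")
})

test_that("a perfectly separating constant feature ranks first with a warning", {
  labels <- rep(c(1, -1), each = 3)
  expect_warning(s <- f_score(c(1, 1, 1, 2, 2, 2), labels), "zero within-class")
  expect_identical(s, Inf)
  vals <- cbind(a = c(1, 1, 1, 2, 2, 2), b = rnorm(6))
  tab <- suppressWarnings(f_score_table(vals, labels))
  expect_equal(tab$ranking[1], 1L)
})

test_that("top-r selection is deterministic under ties and clamps", {
  tab <- list(scores = rep(1, 5), ranking = order(-rep(1, 5), 1:5))
  expect_equal(select_top_r(tab, 3), 1:3)            # ties -> ascending index
  tab2 <- list(scores = c(0.1, 0.9, 0.5), ranking = c(2L, 3L, 1L))
  expect_equal(select_top_r(tab2, 3), c(2L, 3L, 1L)) # r = n: full ranking
  expect_warning(got <- select_top_r(tab2, 10), "clamp")
  expect_length(got, 3)
  expect_error(select_top_r(list(scores = numeric(0)), 1), "empty")
})

test_that("feature TSV export carries provenance header and labels", {
  toy <- toy_trials(n_per_class = 3, C = 8, L = 100)
  fm <- assemble_features(toy$trials, toy$labels, 2, 5, m = 3)
  path <- tempfile(fileext = ".tsv")
  write_features_tsv(fm, path)
  got <- read.delim(path, check.names = FALSE)
  expect_equal(dim(got), c(6, 82))
  expect_equal(got$label, toy$labels)
  expect_true("CSP-TSM(w1):TSM21" %in% names(got))
  unlink(path)
})
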