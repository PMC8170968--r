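#' Pipeline configuration
#'
#' Bundles every tunable of the predictor with the standard protocol as
#' defaults: 7-30 Hz Butterworth band-pass, 0.5-2.5 s cue-relative epoch,
#' three delayed windows, six spatial filters (m = 3 pairs), top 10
#' Fisher-ranked features, an RBF-kernel SVM, delay candidates of 1 to 10%
#' of the sampling rate, and 10 x stratified 10-fold evaluation.
#'
#' @param fs sampling rate in Hz (required; sets the default tau grid).
#' @param band band-pass edges in Hz.
#' @param filter_order Butterworth order.
#' @param zero_phase forward-backward filtering?
#' @param epoch_window cue-relative analysis window in seconds.
#' @param n_windows number of temporally delayed windows.
#' @param m_pairs CSP filter pairs (2*m_pairs spatial filters).
#' @param r features kept after Fisher-score ranking.
#' @param tau_grid integer candidate delays in samples; default
#'   `1:round(0.1*fs)`. A length-1 grid fixes the delay (no inner CV).
#' @param svm_cost soft-margin cost of the SVM.
#' @param svm_gamma RBF width; default `1/r` on standardized features.
#' @param cv_repeats,cv_folds outer evaluation layout.
#' @param inner_folds folds of the inner CV used to select the delay.
#' @param seed base seed for fold assignment; repeat k uses `seed + k - 1`.
#' @return a `spectra_config` list.
#' @export
spectra_config <- function(fs, band = c(7, 30), filter_order = 4,
                           zero_phase = TRUE, epoch_window = c(0.5, 2.5),
                           n_windows = 3, m_pairs = 3, r = 10,
                           tau_grid = NULL, svm_cost = 1, svm_gamma = NULL,
                           cv_repeats = 10, cv_folds = 10, inner_folds = 10,
                           seed = 1) {
  if (is.null(tau_grid)) tau_grid <- seq_len(max(1L, round(0.1 * fs)))
  tau_grid <- as.integer(tau_grid)
  if (length(tau_grid) == 0 || any(tau_grid < 1))
    stop("tau_grid must be nonempty with all delays >= 1")
  if (is.null(svm_gamma)) svm_gamma <- 1 / r
  structure(list(fs = fs, band = band, filter_order = filter_order,
                 zero_phase = zero_phase, epoch_window = epoch_window,
                 n_windows = as.integer(n_windows),
                 m_pairs = as.integer(m_pairs), r = as.integer(r),
                 tau_grid = tau_grid, svm_cost = svm_cost,
                 svm_gamma = svm_gamma,
                 cv_repeats = as.integer(cv_repeats),
                 cv_folds = as.integer(cv_folds),
                 inner_folds = as.integer(inner_folds),
                 seed = as.integer(seed)),
            class = "spectra_config")
}

trials_as_list <- function(ts) {
  lapply(seq_len(n_trials(ts)), function(i) trial_matrix(ts, i))
}

#' Train the full predictor at a fixed temporal delay
#'
#' Fits the CSP-TSM and CSSP-TSM process models, ranks the fused features
#' by Fisher score, keeps the top `r`, standardizes them with
#' training-set statistics, and trains the RBF-kernel SVM. Everything
#' needed for prediction on unseen trials — filter banks, Riemannian
#' means, selected indices, standardizer, SVM — is derived from the
#' training trials only.
#'
#' @param trials a `trial_set` of preprocessed epochs, or a list of
#'   `C x T` matrices.
#' @param labels +1 / -1 labels (taken from the trial set if omitted).
#' @param cfg a [spectra_config()].
#' @param tau temporal delay in samples.
#' @return object of class `spectra_model`.
#' @export
train_spectra <- function(trials, labels = NULL, cfg, tau) {
  if (inherits(trials, "trial_set")) {
    if (is.null(labels)) labels <- trials$labels
    trials <- trials_as_list(trials)
  }
  T_ <- ncol(trials[[1]])
  if ((cfg$n_windows - 1) * tau >= T_)
    stop("delay too large for epoch length")
  fm <- assemble_features(trials, labels, cfg$n_windows, tau, cfg$m_pairs)
  tab <- f_score_table(fm$values, labels)
  sel <- select_top_r(tab, cfg$r)
  X <- fm$values[, sel, drop = FALSE]
  center <- colMeans(X)
  scale_ <- apply(X, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  Xs <- scale(X, center = center, scale = scale_)
  svm_fit <- e1071::svm(x = Xs, y = factor(labels, levels = c(-1, 1)),
                        kernel = "radial", cost = cfg$svm_cost,
                        gamma = cfg$svm_gamma, scale = FALSE)
  structure(list(cfg = cfg, tau = as.integer(tau), models = fm$models,
                 columns = fm$columns, selected = sel,
                 f_scores = tab$scores, center = center, scale = scale_,
                 svm = svm_fit),
            class = "spectra_model")
}

#' Predict task labels for preprocessed trials
#'
#' @param object a `spectra_model`.
#' @param trials a `trial_set` or list of `C x T` matrices, preprocessed
#'   identically to the training data. A single trial works.
#' @param ... unused.
#' @return numeric vector of +1 / -1 predictions.
#' @export
predict.spectra_model <- function(object, trials, ...) {
  if (inherits(trials, "trial_set")) trials <- trials_as_list(trials)
  if (is.matrix(trials)) trials <- list(trials)
  fm <- transform_features(object$models, trials)
  X <- fm$values[, object$selected, drop = FALSE]
  Xs <- scale(X, center = object$center, scale = object$scale)
  as.numeric(as.character(stats::predict(object$svm, Xs)))
}

# stratified fold assignment: per-class round-robin after a seeded shuffle
make_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in c(1, -1)) {
      idx <- which(labels == cl)
      idx <- sample(idx)
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Select the temporal delay by inner cross-validation
#'
#' Runs a stratified inner k-fold cross-validation of the full pipeline
#' for every candidate delay and returns the delay with the smallest mean
#' inner error; ties go to the smallest delay (cheapest for real-time
#' use). Must be called with training data only — the held-out outer fold
#' never enters. A length-1 grid is returned directly.
#'
#' @param trials `trial_set` or list of epoch matrices (training fold).
#' @param labels +1 / -1 labels.
#' @param cfg a [spectra_config()]; uses `tau_grid` and `inner_folds`.
#' @param seed seed for the inner fold assignment (default `cfg$seed`).
#' @return the selected delay (integer samples), with the per-delay mean
#'   inner errors attached as attribute `"inner_errors"`.
#' @export
select_tau <- function(trials, labels = NULL, cfg, seed = cfg$seed) {
  if (inherits(trials, "trial_set")) {
    if (is.null(labels)) labels <- trials$labels
    trials <- trials_as_list(trials)
  }
  grid <- cfg$tau_grid
  if (length(grid) == 1L) return(grid[1])
  folds <- make_folds(labels, cfg$inner_folds, seed)
  errs <- vapply(grid, function(tau) {
    fold_err <- vapply(seq_len(cfg$inner_folds), function(f) {
      tr <- folds != f
      model <- train_spectra(trials[tr], labels[tr], cfg, tau)
      pred <- predict(model, trials[!tr])
      error_rate(labels[!tr], pred)
    }, numeric(1))
    mean(fold_err)
  }, numeric(1))
  tau_star <- grid[order(errs, grid)[1]]          # ties -> smallest delay
  attr(tau_star, "inner_errors") <- stats::setNames(errs, grid)
  tau_star
}

#' Repeated stratified k-fold evaluation of the predictor
#'
#' For each of `cv_repeats` repetitions (fold seeds `seed + repeat - 1`),
#' trials are split into `cv_folds` stratified folds; within every
#' training fold the delay is selected by [select_tau()] (inner CV on the
#' training fold only), the predictor is trained, and error rate and
#' Cohen's kappa are computed on the held-out fold. No held-out
#' information reaches any fitted statistic.
#'
#' @param trials `trial_set` of preprocessed epochs or list of matrices.
#' @param labels +1 / -1 labels.
#' @param cfg a [spectra_config()].
#' @return object of class `cv_report`: `folds` (data.frame with repeat,
#'   fold, tau, error, kappa), `mean_error`, `sd_error`, `mean_kappa`,
#'   `seed`.
#' @export
cross_validate <- function(trials, labels = NULL, cfg) {
  if (inherits(trials, "trial_set")) {
    if (is.null(labels)) labels <- trials$labels
    trials <- trials_as_list(trials)
  }
  n_pos <- sum(labels > 0); n_neg <- sum(labels < 0)
  if (min(n_pos, n_neg) < cfg$cv_folds)
    stop(sprintf("need >= %d trials per class for %d-fold stratified CV",
                 cfg$cv_folds, cfg$cv_folds))
  rows <- list()
  for (rep_i in seq_len(cfg$cv_repeats)) {
    rep_seed <- cfg$seed + rep_i - 1L
    folds <- make_folds(labels, cfg$cv_folds, rep_seed)
    for (f in seq_len(cfg$cv_folds)) {
      tr <- folds != f
      tau <- select_tau(trials[tr], labels[tr], cfg, seed = rep_seed)
      model <- train_spectra(trials[tr], labels[tr], cfg, tau)
      pred <- predict(model, trials[!tr])
      rows[[length(rows) + 1L]] <- data.frame(
        rep = rep_i, fold = f, tau = as.integer(tau),
        error = error_rate(labels[!tr], pred),
        kappa = cohen_kappa(labels[!tr], pred))
    }
  }
  folds_df <- do.call(rbind, rows)
  structure(list(folds = folds_df,
                 mean_error = mean(folds_df$error),
                 sd_error = stats::sd(folds_df$error),
                 mean_kappa = mean(folds_df$kappa),
                 seed = cfg$seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d folds: error %.2f%% +/- %.2f, kappa %.3f (%s)\n",
              nrow(x$folds), x$mean_error, x$sd_error, x$mean_kappa,
              kappa_strength(max(-1, min(1, x$mean_kappa)))))
  invisible(x)
}

#' Classification error rate in percent
#'
#' @param true,predicted equal-length +1 / -1 vectors.
#' @return `100 * mean(true != predicted)`.
#' @export
error_rate <- function(true, predicted) {
  if (length(true) == 0) stop("empty input")
  if (length(true) != length(predicted)) stop("length mismatch")
  100 * mean(true != predicted)
}

#' Cohen's kappa for binary agreement
#'
#' `kappa = (p_a - p_e) / (1 - p_e)` with `p_a` the observed agreement
#' proportion and `p_e` the agreement expected by chance from the
#' confusion-matrix marginals. Perfect agreement gives 1 by convention
#' even when `p_e = 1`; a degenerate `p_e = 1` with imperfect agreement
#' returns 0 with a warning.
#'
#' @param true,predicted equal-length +1 / -1 vectors.
#' @return scalar in `[-1, 1]`.
#' @export
cohen_kappa <- function(true, predicted) {
  if (length(true) == 0) stop("empty input")
  if (length(true) != length(predicted)) stop("length mismatch")
  n <- length(true)
  p_a <- mean(true == predicted)
  if (p_a == 1) return(1)
  lv <- c(-1, 1)
  tab <- table(factor(true, levels = lv), factor(predicted, levels = lv))
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (p_e == 1) {
    warning("degenerate marginals (p_e = 1); kappa defined as 0")
    return(0)
  }
  (p_a - p_e) / (1 - p_e)
}

#' Qualitative strength of agreement for a kappa value
#'
#' Maps kappa to the conventional bands Poor (< 0.20), Fair (0.21-0.40),
#' Moderate (0.41-0.60), Good (0.61-0.80), Very Good (0.81-1.0). Because
#' the printed bands are non-contiguous, the value is rounded to two
#' decimals before banding.
#'
#' @param kappa scalar in `[-1, 1]`.
#' @return one of "Poor", "Fair", "Moderate", "Good", "Very Good".
#' @export
kappa_strength <- function(kappa) {
  if (!is.finite(kappa) || kappa < -1 || kappa > 1)
    stop("kappa must lie in [-1, 1]")
  k <- round(kappa, 2)
  if (k <= 0.20) "Poor"
  else if (k <= 0.40) "Fair"
  else if (k <= 0.60) "Moderate"
  else if (k <= 0.80) "Good"
  else "Very Good"
}
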