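# materialise the input matrix of one process for one trial's windows
process_input <- function(windows, proc) {
  if (is.na(proc$window_j)) windows[[proc$window_i]]
  else rbind(windows[[proc$window_i]], windows[[proc$window_j]])
}

process_label <- function(proc) {
  if (is.na(proc$window_j)) sprintf("CSP-TSM(w%d)", proc$window_i)
  else sprintf("CSSP-TSM(w%d,w%d)", proc$window_i, proc$window_j)
}

#' Fit one CSP-TSM / CSSP-TSM process on training trials
#'
#' Builds the process's input (a single delayed window, or a delay-embedded
#' channel stack of a window pair) for every training trial, learns the CSP
#' filter bank on it, and computes the Riemannian mean of the filtered
#' trial covariances. The mean is learned on training trials only and
#' stored so unseen trials are projected into the same tangent space.
#'
#' @param trials list of `C x T` epoch matrices (training set).
#' @param labels +1 / -1 labels.
#' @param proc one row of [spectra_processes()].
#' @param n_windows,tau window layout passed to [make_windows()].
#' @param m CSP filter pairs (default 3, i.e. six spatial filters).
#' @return object of class `process_model`.
#' @export
fit_process <- function(trials, labels, proc, n_windows, tau, m = 3) {
  inputs <- lapply(trials, function(x)
    process_input(make_windows(x, n_windows, tau), proc))
  bank <- learn_csp(inputs, labels, m)
  covs <- lapply(inputs, function(X) trial_covariance(apply_filters(bank, X)))
  rmean <- riemannian_mean(covs)
  structure(list(proc = proc, bank = bank, rmean = rmean,
                 n_windows = n_windows, tau = tau, m = m),
            class = "process_model")
}

#' Feature block of one fitted process
#'
#' For each trial: the `2m` log-variance CSP features of the filtered
#' signal followed by the `d(d+1)/2` tangent-space features of its
#' covariance at the stored training mean — 27 features per process for
#' the default six filters.
#'
#' @param model a `process_model` from [fit_process()].
#' @param trials list of `C x T` epoch matrices (train or unseen).
#' @return matrix `n_trials x (2m + d(d+1)/2)`.
#' @export
transform_process <- function(model, trials) {
  stopifnot(inherits(model, "process_model"))
  d <- 2 * model$m
  n_feat <- d + d * (d + 1) / 2
  out <- matrix(NA_real_, length(trials), n_feat)
  for (i in seq_along(trials)) {
    X <- process_input(make_windows(trials[[i]], model$n_windows, model$tau),
                       model$proc)
    Z <- apply_filters(model$bank, X)
    out[i, ] <- c(csp_features(Z),
                  tangent_vector(model$rmean, trial_covariance(Z)))
  }
  out
}

#' Fit all processes and assemble the fused feature matrix
#'
#' Runs the `n` plain-window CSP-TSM processes and the `n(n-1)/2`
#' delay-embedded CSSP-TSM processes in fixed order and concatenates their
#' feature blocks: `(n + n(n-1)/2) * 27` columns for the defaults
#' (`n = 3`, six filters), i.e. 162. Column metadata records the process,
#' feature kind (CSP or TSM) and within-block index for every column, so a
#' selected feature index maps back to its origin.
#'
#' @param trials list of `C x T` epoch matrices (training set).
#' @param labels +1 / -1 labels.
#' @param n_windows,tau window layout.
#' @param m CSP filter pairs.
#' @return list with `values` (feature matrix), `columns` (metadata
#'   data.frame), `labels`, and `models` (fitted `process_model`s).
#' @export
assemble_features <- function(trials, labels, n_windows, tau, m = 3) {
  procs <- spectra_processes(n_windows)
  models <- lapply(seq_len(nrow(procs)), function(k)
    fit_process(trials, labels, procs[k, ], n_windows, tau, m))
  out <- transform_features(models, trials)
  out$labels <- labels
  out$models <- models
  out
}

#' Apply fitted process models to (possibly unseen) trials
#'
#' @param models list of `process_model`s from [assemble_features()].
#' @param trials list of `C x T` epoch matrices.
#' @return list with `values` and `columns` as in [assemble_features()].
#' @export
transform_features <- function(models, trials) {
  blocks <- lapply(models, transform_process, trials = trials)
  meta <- do.call(rbind, lapply(models, function(mod) {
    d <- 2 * mod$m
    n_tsm <- d * (d + 1) / 2
    data.frame(process = process_label(mod$proc),
               kind = c(rep("CSP", d), rep("TSM", n_tsm)),
               local = c(seq_len(d), seq_len(n_tsm)))
  }))
  values <- do.call(cbind, blocks)
  colnames(values) <- paste0(meta$process, ":", meta$kind, meta$local)
  list(values = values, columns = meta)
}

#' Fisher score of a single feature column
#'
#' Ratio of the squared deviations of the class means from the grand mean
#' to the sum of the unbiased within-class variances. Zero when the class
#' distributions coincide; infinite (with a warning) for a feature that
#' separates the classes with zero within-class variance — such a feature
#' is maximally informative and ranks first.
#'
#' @param x numeric feature column.
#' @param labels +1 / -1 labels, each class with >= 2 samples.
#' @return nonnegative scalar (possibly `Inf`).
#' @export
f_score <- function(x, labels) {
  pos <- x[labels > 0]; neg <- x[labels < 0]
  if (length(pos) < 2 || length(neg) < 2)
    stop("each class needs >= 2 samples")
  num <- (mean(pos) - mean(x))^2 + (mean(neg) - mean(x))^2
  den <- stats::var(pos) + stats::var(neg)
  if (den == 0) {
    if (num == 0) return(0)
    warning("zero within-class variance: feature separates classes exactly")
    return(Inf)
  }
  num / den
}

#' Fisher scores of every column of a feature matrix
#'
#' @param values `n_trials x n_features` matrix.
#' @param labels +1 / -1 labels.
#' @return list with `scores` and `ranking` (indices sorted by descending
#'   score, ties broken by ascending index).
#' @export
f_score_table <- function(values, labels) {
  scores <- apply(values, 2, f_score, labels = labels)
  list(scores = scores, n_pos = sum(labels > 0), n_neg = sum(labels < 0),
       ranking = order(-scores, seq_along(scores)))
}

#' Select the r highest-scoring features
#'
#' @param table result of [f_score_table()].
#' @param r number of features to keep (default 10); clamped with a
#'   warning when it exceeds the number of features.
#' @return integer vector of `r` column indices.
#' @export
select_top_r <- function(table, r = 10) {
  n <- length(table$scores)
  if (n == 0) stop("empty feature table")
  if (r < 1) stop("r must be >= 1")
  if (r > n) {
    warning("r exceeds feature count; clamping to ", n)
    r <- n
  }
  table$ranking[seq_len(r)]
}

#' Export a feature matrix as tab-separated values
#'
#' The header row carries per-column provenance
#' (`process:kindIndex`), the first column the trial label.
#'
#' @param fm result of [assemble_features()] / [transform_features()]
#'   (with `labels` present).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_features_tsv <- function(fm, path) {
  df <- data.frame(label = fm$labels, fm$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
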