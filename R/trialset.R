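#' Construct a labelled trial set
#'
#' A trial set holds epoched multichannel EEG: one `C x T` matrix per trial,
#' a binary task label per trial, and the sampling rate. It is the common
#' currency of every stage of the pipeline.
#'
#' @param data numeric 3-d array, `n_trials x n_channels x n_samples`.
#' @param labels numeric vector of `+1` / `-1` task labels, one per trial.
#' @param fs sampling rate in Hz.
#' @param channel_names optional character vector of channel names.
#' @return An object of class `trial_set`.
#' @export
trial_set <- function(data, labels, fs, channel_names = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-d array (trials x channels x samples)")
  d <- dim(data)
  if (d[1] < 1L) stop("trial set must contain at least one trial")
  if (length(labels) != d[1])
    stop("length(labels) must equal the number of trials")
  if (!all(labels %in% c(-1, 1)))
    stop("labels must be +1 or -1")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number")
  if (anyNA(data) || any(!is.finite(data)))
    stop("trial data contains NaN or non-finite values")
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(d[2]))
  if (length(channel_names) != d[2])
    stop("channel_names length must equal the number of channels")
  structure(
    list(data = data, labels = as.numeric(labels), fs = as.numeric(fs),
         channel_names = as.character(channel_names)),
    class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<trial_set> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat(sprintf("  labels: %d positive (+1), %d negative (-1)\n",
              sum(x$labels == 1), sum(x$labels == -1)))
  invisible(x)
}

#' Number of trials in a trial set
#' @param ts a `trial_set`.
#' @return integer count.
#' @export
n_trials <- function(ts) dim(ts$data)[1]

#' Extract one trial as a channels-by-samples matrix
#' @param ts a `trial_set`.
#' @param i trial index (1-based).
#' @return `C x T` numeric matrix.
#' @export
trial_matrix <- function(ts, i) {
  m <- ts$data[i, , , drop = TRUE]
  matrix(m, nrow = dim(ts$data)[2], ncol = dim(ts$data)[3])
}

#' Replace every trial with the result of a per-trial transform
#'
#' @param ts a `trial_set`.
#' @param f function taking a `C x T` matrix and returning a matrix with the
#'   same number of channels (samples may change, e.g. after epoching).
#' @return a new `trial_set`.
#' @export
map_trials <- function(ts, f) {
  first <- f(trial_matrix(ts, 1))
  n <- n_trials(ts)
  out <- array(NA_real_, c(n, nrow(first), ncol(first)))
  out[1, , ] <- first
  if (n > 1) for (i in 2:n) out[i, , ] <- f(trial_matrix(ts, i))
  trial_set(out, ts$labels, ts$fs, ts$channel_names[seq_len(nrow(first))])
}

#' Subset a trial set by trial index
#' @param ts a `trial_set`.
#' @param idx integer indices of trials to keep.
#' @return a new `trial_set`.
#' @export
subset_trials <- function(ts, idx) {
  trial_set(ts$data[idx, , , drop = FALSE], ts$labels[idx], ts$fs,
            ts$channel_names)
}

#' Write a trial set to a portable on-disk archive
#'
#' The archive is a directory containing `meta.yaml` (sampling rate, shape,
#' labels, channel names, dtype, byte order, optional provenance seed) and
#' `data.bin`, a raw little-endian float64 array in row-major
#' trial-channel-sample order. The round trip is bit-exact, and the format
#' is readable from any language.
#'
#' @param ts a `trial_set`.
#' @param path directory to create.
#' @param overwrite overwrite an existing archive? Default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_trialset <- function(ts, path, overwrite = FALSE) {
  stopifnot(inherits(ts, "trial_set"))
  if (dir.exists(path) || file.exists(path)) {
    if (!overwrite) stop("path exists; use overwrite = TRUE: ", path)
    unlink(path, recursive = TRUE)
  }
  dir.create(path, recursive = TRUE)
  d <- dim(ts$data)
  meta <- list(
    format = "spectra-trialset-v1",
    fs = ts$fs,
    n_trials = d[1], n_channels = d[2], n_samples = d[3],
    dtype = "float64", byte_order = "little", order = "row-major",
    labels = as.integer(ts$labels),
    channel_names = ts$channel_names)
  seed <- attr(ts, "seed")
  if (!is.null(seed)) meta$seed <- as.integer(seed)
  yaml::write_yaml(meta, file.path(path, "meta.yaml"))
  con <- file(file.path(path, "data.bin"), "wb")
  on.exit(close(con))
  # row-major = samples fastest: permute so R's column-major flattening matches
  writeBin(as.numeric(aperm(ts$data, c(3, 2, 1))), con,
           size = 8, endian = "little")
  invisible(path)
}

#' Read a trial-set archive written by [write_trialset()]
#'
#' Validates shape, byte length, label domain and finiteness before
#' returning; a mismatch between `meta.yaml` and `data.bin` is an error.
#'
#' @param path archive directory.
#' @return a `trial_set`.
#' @export
read_trialset <- function(path) {
  mf <- file.path(path, "meta.yaml")
  bf <- file.path(path, "data.bin")
  if (!file.exists(mf) || !file.exists(bf))
    stop("not a trial-set archive (missing meta.yaml or data.bin): ", path)
  meta <- yaml::read_yaml(mf)
  if (!identical(meta$format, "spectra-trialset-v1"))
    stop("unknown archive format: ", meta$format)
  if (!identical(meta$dtype, "float64"))
    stop("unknown dtype in archive: ", meta$dtype)
  n <- meta$n_trials; C <- meta$n_channels; T_ <- meta$n_samples
  expect_bytes <- 8 * n * C * T_
  if (file.size(bf) != expect_bytes)
    stop(sprintf("data.bin has %d bytes, metadata implies %d",
                 file.size(bf), expect_bytes))
  con <- file(bf, "rb")
  on.exit(close(con))
  vec <- readBin(con, "numeric", n = n * C * T_, size = 8, endian = "little")
  if (anyNA(vec) || any(!is.finite(vec)))
    stop("data.bin contains NaN or non-finite values")
  data <- aperm(array(vec, c(T_, C, n)), c(3, 2, 1))
  trial_set(data, as.numeric(meta$labels), meta$fs,
            as.character(meta$channel_names))
}
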