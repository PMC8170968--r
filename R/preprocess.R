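#' Common average reference
#'
#' Subtracts the instantaneous mean across channels from every sample, the
#' standard re-referencing step for motor-imagery pipelines. Idempotent.
#'
#' @param x `C x T` numeric matrix (channels by samples), `C >= 2`.
#' @return matrix of the same shape with zero channel-mean at every sample.
#' @export
common_average_reference <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("common average reference needs >= 2 channels")
  sweep(x, 2, colMeans(x))
}

#' Butterworth band-pass filter
#'
#' Filters each channel with a Butterworth band-pass designed by
#' [signal::butter()]. By default the filter is applied forward-backward
#' ([signal::filtfilt()]) so the output is zero-phase: epochs keep their
#' temporal alignment to the cue, at the price of an effectively doubled
#' filter order.
#'
#' @param x `C x T` numeric matrix.
#' @param fs sampling rate in Hz.
#' @param low,high band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @param order filter order (default 4).
#' @param zero_phase apply forward-backward? Default `TRUE`.
#' @return filtered matrix of the same shape.
#' @export
bandpass_filter <- function(x, fs, low = 7, high = 30, order = 4,
                            zero_phase = TRUE) {
  x <- as.matrix(x)
  if (!(low > 0 && low < high && high < fs / 2))
    stop("band must satisfy 0 < low < high < fs/2")
  if (order < 1) stop("order must be >= 1")
  if (ncol(x) <= 3 * order)
    stop("too few samples for a stable order-", order, " filter")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  out <- x
  for (i in seq_len(nrow(x))) {
    out[i, ] <- if (zero_phase) signal::filtfilt(bf, x[i, ])
                else as.numeric(signal::filter(bf, x[i, ]))
  }
  out
}

#' Extract a cue-relative epoch from a continuous record
#'
#' Returns samples `[cue + round(t_start*fs), cue + round(t_end*fs))` —
#' half-open, with 0-based sample indexing — so epoch boundaries are pure
#' integer arithmetic and reproducible across platforms.
#'
#' @param record `C x N` numeric matrix of continuous data.
#' @param fs sampling rate in Hz.
#' @param cue_sample 0-based sample index of the cue.
#' @param window numeric length-2 `(t_start_s, t_end_s)` relative to cue.
#' @param trial optional trial identifier used in error messages.
#' @return `C x round((t_end-t_start)*fs)` matrix.
#' @export
extract_epoch <- function(record, fs, cue_sample, window, trial = NA) {
  record <- as.matrix(record)
  i0 <- cue_sample + round(window[1] * fs)
  i1 <- cue_sample + round(window[2] * fs)
  lab <- if (is.na(trial)) "" else paste0(" (trial ", trial, ")")
  if (i1 <= i0)
    stop("empty epoch window", lab)
  if (i0 < 0 || i1 > ncol(record))
    stop(sprintf("epoch [%d, %d) exceeds record of %d samples%s",
                 i0, i1, ncol(record), lab))
  record[, (i0 + 1):i1, drop = FALSE]
}

#' Preprocess a trial set with the standard protocol
#'
#' Per trial: common average referencing, Butterworth band-pass (7-30 Hz by
#' default), then extraction of the cue-relative analysis window when the
#' trial is longer than the window (the cue is taken at sample 0 of each
#' pre-epoched trial). This mirrors the usual motor-imagery protocol of
#' analysing 0.5-2.5 s after the visual cue.
#'
#' @param ts a `trial_set`.
#' @param band numeric length-2 band edges in Hz.
#' @param order Butterworth order.
#' @param zero_phase forward-backward filtering?
#' @param epoch_window numeric length-2 `(t_start_s, t_end_s)` relative to
#'   trial start, or `NULL` to keep whole trials.
#' @return a preprocessed `trial_set`.
#' @export
preprocess_trials <- function(ts, band = c(7, 30), order = 4,
                              zero_phase = TRUE, epoch_window = c(0.5, 2.5)) {
  stopifnot(inherits(ts, "trial_set"))
  fs <- ts$fs
  T_ <- dim(ts$data)[3]
  do_epoch <- !is.null(epoch_window) &&
    round(epoch_window[2] * fs) <= T_ &&
    round((epoch_window[2] - epoch_window[1]) * fs) < T_
  map_trials(ts, function(x) {
    x <- common_average_reference(x)
    x <- bandpass_filter(x, fs, band[1], band[2], order, zero_phase)
    if (do_epoch) x <- extract_epoch(x, fs, 0L, epoch_window)
    x
  })
}
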