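#' Re-reference a recording to the common average
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' that the per-sample channel mean of the output is zero.
#'
#' @param rec An `eeg_recording` with at least two channels.
#' @return The re-referenced `eeg_recording`.
#' @export
average_reference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$data) < 2L)
    stop("average reference requires at least two channels")
  out <- rec
  out$data <- sweep(rec$data, 2, colMeans(rec$data))
  out$reference <- "common average"
  out
}

#' Zero-phase band-pass filter a recording
#'
#' Cascaded Butterworth high-pass and low-pass sections, each applied
#' forward and backward (`signal::filtfilt`), so the net filter has zero
#' phase and twice the nominal order. The cascade is used instead of a
#' single band-pass prototype because the low edge (0.5 Hz at 256 Hz
#' sampling) sits deep in the normalized band where a combined band-pass
#' transfer polynomial is numerically fragile.
#'
#' @param rec An `eeg_recording`.
#' @param low,high Band edges in Hz; must satisfy 0 < low < high < fs/2.
#' @param order Butterworth order per section per pass. Default 4.
#' @return The filtered `eeg_recording`.
#' @export
bandpass_filter <- function(rec, low = 0.5, high = 30, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (!(low > 0 && low < high && high < nyq))
    stop("band edges must satisfy 0 < low < high < fs/2 (fs/2 = ", nyq, " Hz)")
  hp <- signal::butter(order, low / nyq, type = "high")
  lp <- signal::butter(order, high / nyq, type = "low")
  out <- rec
  for (i in seq_len(nrow(rec$data))) {
    x <- signal::filtfilt(hp, rec$data[i, ])
    out$data[i, ] <- signal::filtfilt(lp, x)
  }
  out
}

#' Construct a discharge-centred segment
#'
#' @param data Channels x samples matrix.
#' @param fs Sampling rate in Hz.
#' @param t0_index 0-based sample offset of the labeled discharge peak
#'   within `data` (the peak sample is `data[, t0_index + 1]`).
#' @param event The originating event row (one-row `discharge_events`), or
#'   `NULL`.
#' @param channel_labels Channel labels.
#' @param burn_in Number of leading samples that are filter burn-in
#'   context rather than part of the analysis window (default 0; see
#'   [extract_segments()]).
#' @return An object of class `eeg_segment`.
#' @export
eeg_segment <- function(data, fs, t0_index, event = NULL,
                        channel_labels = rownames(data), burn_in = 0L) {
  data <- as.matrix(data)
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(nrow(data)))
  rownames(data) <- channel_labels
  structure(list(data = data, fs = as.numeric(fs),
                 t0_index = as.integer(t0_index), event = event,
                 channel_labels = as.character(channel_labels),
                 burn_in = as.integer(burn_in)),
            class = "eeg_segment")
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf(
    "<eeg_segment> %d channels x %d samples @ %g Hz, peak at offset %d (%+.3f .. %+.3f s)\n",
    nrow(x$data), ncol(x$data), x$fs, x$t0_index,
    -x$t0_index / x$fs, (ncol(x$data) - 1 - x$t0_index) / x$fs))
  invisible(x)
}

#' Time axis of a segment relative to the discharge peak
#' @param seg An `eeg_segment`.
#' @return Numeric vector of times in seconds (0 at the labeled peak).
#' @export
segment_times <- function(seg) {
  (seq_len(ncol(seg$data)) - 1 - seg$t0_index) / seg$fs
}

#' Extract discharge-centred segments
#'
#' For each event, the peak time is mapped to the sample index
#' `round(peak_time * fs)` (0-based) and the half-open window of
#' `half_width` seconds on either side is cut out, giving
#' `2 * half_width * fs` samples with the peak at offset `half_width * fs`.
#' Events whose window does not fit inside the recording are dropped with a
#' warning.
#'
#' @param rec A preprocessed `eeg_recording`.
#' @param events A `discharge_events` data.frame.
#' @param half_width Seconds before and after the peak. Default 3.
#' @param burn_in_s Seconds of extra left context prepended for Kalman
#'   filter burn-in. The analysis window (and every downstream network
#'   grid) remains the `2 * half_width` epoch around the peak; the
#'   context only gives the coefficient tracker history, and is trimmed
#'   from connectivity results. Default 0.
#' @return List of `eeg_segment` objects, in event order.
#' @export
extract_segments <- function(rec, events, half_width = 3, burn_in_s = 0) {
  stopifnot(inherits(rec, "eeg_recording"))
  half <- as.integer(round(half_width * rec$fs))
  burn <- as.integer(round(burn_in_s * rec$fs))
  n <- ncol(rec$data)
  out <- list()
  for (r in seq_len(nrow(events))) {
    pk <- as.integer(round(events$peak_time_s[r] * rec$fs))  # 0-based
    start <- pk - half - burn                                 # 0-based, inclusive
    end <- pk + half                                          # exclusive
    if (start < 0L || end > n) {
      warning("event at ", events$peak_time_s[r],
              " s too close to a recording edge; dropped")
      next
    }
    out[[length(out) + 1L]] <- eeg_segment(
      rec$data[, (start + 1L):end, drop = FALSE], rec$fs,
      t0_index = half + burn, event = events[r, , drop = FALSE],
      channel_labels = rec$channel_labels, burn_in = burn)
  }
  out
}

#' Decimate a segment
#'
#' Applies a zero-phase Butterworth anti-aliasing low-pass (cutoff at 80%
#' of the post-decimation Nyquist) and keeps every `factor`-th sample,
#' starting from the first. The segment length must be divisible by
#' `factor`; the 6-s, 256 Hz discharge segments decimated by the default
#' factor 8 come out as 192 samples at 32 Hz with the peak at offset 96.
#'
#' @param seg An `eeg_segment`.
#' @param factor Integer decimation factor. Default 8.
#' @param aa_order Anti-alias Butterworth order per pass. Default 6.
#' @return The decimated `eeg_segment`.
#' @export
decimate_segment <- function(seg, factor = 8, aa_order = 6) {
  stopifnot(inherits(seg, "eeg_segment"))
  factor <- as.integer(factor)
  if (factor < 1L) stop("decimation factor must be >= 1")
  if (factor == 1L) return(seg)
  n <- ncol(seg$data)
  if (n %% factor != 0L)
    stop("segment length ", n, " is not divisible by factor ", factor)
  aa <- signal::butter(aa_order, 0.8 / factor, type = "low")
  filt <- t(apply(seg$data, 1, function(x) signal::filtfilt(aa, x)))
  keep <- seq(1L, n, by = factor)
  eeg_segment(filt[, keep, drop = FALSE], seg$fs / factor,
              t0_index = seg$t0_index %/% factor, event = seg$event,
              channel_labels = seg$channel_labels,
              burn_in = (seg$burn_in %||% 0L) %/% factor)
}

#' Preprocess and epoch a recording in the standard order
#'
#' Convenience wrapper: common-average reference, band-pass filter,
#' discharge-centred epoching, decimation.
#'
#' @param rec An `eeg_recording`.
#' @param events A `discharge_events` data.frame.
#' @param low,high Band-pass edges in Hz. Defaults 0.5 and 30.
#' @param half_width Segment half width in seconds. Default 3.
#' @param factor Decimation factor. Default 8.
#' @param reref Apply the common-average reference. Default `TRUE`.
#' @param burn_in_s Left filter-burn-in context in seconds (see
#'   [extract_segments()]). Default 0.
#' @return List of decimated `eeg_segment` objects.
#' @export
preprocess_segments <- function(rec, events, low = 0.5, high = 30,
                                half_width = 3, factor = 8, reref = TRUE,
                                burn_in_s = 0) {
  if (reref) rec <- average_reference(rec)
  rec <- bandpass_filter(rec, low, high)
  segs <- extract_segments(rec, events, half_width, burn_in_s)
  lapply(segs, decimate_segment, factor = factor)
}
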