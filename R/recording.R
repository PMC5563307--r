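#' Construct an EEG recording object
#'
#' A recording holds a channels-by-samples signal matrix (microvolts), the
#' sampling rate and the montage labels. All pipeline stages operate on this
#' container.
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param channel_labels Character vector of unique montage names, one per
#'   row of `data`.
#' @param reference Free-text description of the reference scheme.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels = rownames(data),
                          reference = "as recorded") {
  data <- as.matrix(data)
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(nrow(data)))
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data))
    stop("one channel label per data row is required")
  if (anyDuplicated(channel_labels))
    stop("channel labels must be unique")
  if (!is.numeric(fs) || length(fs) != 1L || !(fs > 0))
    stop("fs must be a positive scalar (Hz)")
  storage.mode(data) <- "double"
  rownames(data) <- channel_labels
  structure(list(data = data, fs = as.numeric(fs),
                 channel_labels = channel_labels,
                 reference = reference),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  cat("  reference:", x$reference, "\n")
  invisible(x)
}

#' Recording duration in seconds
#' @param rec An `eeg_recording`.
#' @return Duration in seconds.
#' @export
recording_duration <- function(rec) ncol(rec$data) / rec$fs

# ---- EDF/EDF+ I/O -----------------------------------------------------
# Minimal European Data Format support: fixed-width ASCII header (256 bytes
# + 256 per signal) followed by data records of 16-bit little-endian
# integers, linearly mapped between the digital and physical ranges.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

.edf_num <- function(x, width) .edf_pad(format(x, scientific = FALSE, trim = TRUE), width)

#' Write a recording to an EDF file
#'
#' Samples are scaled to 16-bit integers over the physical range observed in
#' the data (per channel). Record duration is 1 s, so `fs` samples per
#' record per channel; the recording is truncated to a whole number of
#' records.
#'
#' @param rec An `eeg_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  ns <- nrow(rec$data)
  spr <- as.integer(round(rec$fs))          # samples per 1-s record
  if (abs(spr - rec$fs) > 1e-9)
    stop("write_edf requires an integer sampling rate")
  n_rec <- ncol(rec$data) %/% spr
  if (n_rec < 1) stop("recording shorter than one 1-s data record")
  ntot <- n_rec * spr

  pmin_ <- apply(rec$data[, seq_len(ntot), drop = FALSE], 1, min)
  pmax_ <- apply(rec$data[, seq_len(ntot), drop = FALSE], 1, max)
  # avoid a degenerate physical range
  flat <- (pmax_ - pmin_) < 1e-6
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768L; dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8),                       # version
    .edf_pad("X X X X", 80),                # patient id (anonymous)
    .edf_pad("Startdate X X X X", 80),      # recording id
    .edf_pad("01.01.00", 8), .edf_pad("00.00.00", 8),
    .edf_num(256 + ns * 256, 8),
    .edf_pad("", 44),
    .edf_num(n_rec, 8),
    .edf_num(1, 8),                         # record duration, s
    .edf_num(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- c(
    vapply(rec$channel_labels, .edf_pad, "", width = 16),
    rep(.edf_pad("", 80), ns),              # transducer
    rep(.edf_pad("uV", 8), ns),
    vapply(sprintf("%.6g", pmin_), .edf_pad, "", width = 8),
    vapply(sprintf("%.6g", pmax_), .edf_pad, "", width = 8),
    rep(.edf_num(dmin, 8), ns),
    rep(.edf_num(dmax, 8), ns),
    rep(.edf_pad("", 80), ns),              # prefiltering
    rep(.edf_num(spr, 8), ns),
    rep(.edf_pad("", 32), ns))
  writeChar(paste(fields, collapse = ""), con, eos = NULL)

  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    dig <- round((rec$data[, idx, drop = FALSE] - pmin_) * scale) + dmin
    dig <- pmin(pmax(dig, dmin), dmax)
    # channel-sequential within each record
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF/EDF+ file
#'
#' Reads a subset of channels selected by label. All selected channels must
#' share one sampling rate; channels such as ECG/EMG are excluded simply by
#' not listing them.
#'
#' @param path Path to an EDF/EDF+ file.
#' @param channels Optional character vector of channel labels to keep (in
#'   the given order). Default: all channels.
#' @return An `eeg_recording`.
#' @export
read_edf <- function(path, channels = NULL) {
  if (!file.exists(path)) stop("cannot read EDF file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd_s <- function(n) {
    raw <- readBin(con, "raw", n)
    if (length(raw) < n) stop("truncated EDF header: ", path)
    trimws(rawToChar(raw))
  }
  rd_s(8)                                    # version
  rd_s(80); rd_s(80); rd_s(8); rd_s(8)
  hdr_bytes <- as.integer(rd_s(8))
  rd_s(44)
  n_rec <- as.integer(rd_s(8))
  rec_dur <- as.numeric(rd_s(8))
  ns <- as.integer(rd_s(4))
  if (is.na(ns) || ns < 1 || is.na(n_rec) || is.na(rec_dur) || rec_dur <= 0)
    stop("malformed EDF header: ", path)

  fld <- function(width) vapply(seq_len(ns), function(i) rd_s(width), "")
  labels <- fld(16)
  fld(80); fld(8)
  pmin_ <- as.numeric(fld(8)); pmax_ <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8))
  fld(32)
  stopifnot(hdr_bytes == 256 + ns * 256)

  sel <- seq_len(ns)
  if (!is.null(channels)) {
    missing_lab <- setdiff(channels, labels)
    if (length(missing_lab))
      stop("requested channel(s) not present in EDF: ",
           paste(missing_lab, collapse = ", "))
    sel <- match(channels, labels)
  }
  fs_sel <- spr[sel] / rec_dur
  if (length(unique(fs_sel)) != 1L)
    stop("selected channels have mixed sampling rates: ",
         paste(unique(fs_sel), collapse = ", "))
  fs <- fs_sel[1]

  out <- matrix(0, length(sel), n_rec * spr[sel[1]])
  offs <- c(0L, cumsum(spr))                 # per-record sample offsets
  rec_len <- sum(spr)
  for (r in seq_len(n_rec)) {
    rec_raw <- readBin(con, "integer", n = rec_len, size = 2,
                       endian = "little", signed = TRUE)
    if (length(rec_raw) < rec_len) stop("truncated EDF data record ", r)
    for (k in seq_along(sel)) {
      i <- sel[k]
      smp <- rec_raw[(offs[i] + 1):(offs[i] + spr[i])]
      out[k, ((r - 1) * spr[i] + 1):(r * spr[i])] <-
        (smp - dmin[i]) * (pmax_[i] - pmin_[i]) / (dmax[i] - dmin[i]) + pmin_[i]
    }
  }
  eeg_recording(out, fs, labels[sel], reference = "as recorded (EDF)")
}

# ---- discharge events -------------------------------------------------

#' Construct discharge events
#'
#' @param peak_time Numeric vector of inter-ictal discharge peak times,
#'   seconds from recording start.
#' @param label Optional annotator tags (recycled).
#' @return A data.frame of class `discharge_events` with columns
#'   `peak_time_s` and `label`, sorted by time.
#' @export
discharge_events <- function(peak_time, label = NA_character_) {
  peak_time <- as.numeric(peak_time)
  if (any(!is.finite(peak_time))) stop("non-finite peak time")
  df <- data.frame(peak_time_s = peak_time,
                   label = rep_len(as.character(label), length(peak_time)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$peak_time_s), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("discharge_events", "data.frame")
  df
}

#' Read discharge events from CSV
#'
#' The file must have a header `peak_time_s` with an optional second column
#' `label`; one labeled discharge peak per row, in seconds from recording
#' start. Events closer than `margin` seconds to either edge of the
#' recording are dropped with a warning, so that a full segment fits.
#'
#' @param path CSV file path.
#' @param duration Recording duration in seconds; if supplied, the margin
#'   rule is applied.
#' @param margin Required distance (s) from the recording edges. Default 3.
#' @return A `discharge_events` data.frame (possibly empty).
#' @export
read_events <- function(path, duration = NULL, margin = 3) {
  if (!file.exists(path)) stop("cannot read events file: ", path)
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("malformed events CSV: ",
                                          conditionMessage(e)))
  if (nrow(df) == 0L) {
    warning("events file contains no events: ", path)
    return(discharge_events(numeric(0)))
  }
  if (!"peak_time_s" %in% names(df))
    stop("events CSV must have a 'peak_time_s' column")
  pk <- suppressWarnings(as.numeric(df$peak_time_s))
  bad <- which(!is.finite(pk))
  if (length(bad))
    stop("malformed peak_time_s on line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path)
  lab <- if ("label" %in% names(df)) as.character(df$label) else NA_character_
  ev <- discharge_events(pk, lab)
  if (!is.null(duration)) {
    keep <- ev$peak_time_s >= margin & ev$peak_time_s <= duration - margin
    if (any(!keep))
      warning(sum(!keep), " event(s) dropped: closer than ", margin,
              " s to a recording edge")
    ev <- ev[keep, , drop = FALSE]
    class(ev) <- c("discharge_events", "data.frame")
  }
  ev
}

#' Write discharge events to CSV
#' @param events A `discharge_events` data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  write.csv(as.data.frame(events)[, c("peak_time_s", "label")], path,
            row.names = FALSE)
  invisible(path)
}
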