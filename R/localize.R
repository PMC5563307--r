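# Epileptogenic-zone localization from the binarized out-degree matrix:
# the EZ electrode is the earliest non-background channel with sustained
# strong outflow after the baseline window.

#' Time-varying out-degree of a binary dynamic network
#'
#' `k[j, t]` counts the significant edges leaving node `j` at time `t`
#' (self-edges excluded by construction of the network).
#'
#' @param net A `binary_dynamic_network`.
#' @return Object of class `out_degree`: integer matrix `k`
#'   (`[node, time]`, `NA` before estimates exist), `channel_labels`,
#'   `times` (seconds relative to the discharge peak).
#' @export
out_degree_matrix <- function(net) {
  stopifnot(inherits(net, "binary_dynamic_network"))
  N <- dim(net$adj)[3]
  k <- sapply(seq_len(N), function(t) colSums(net$adj[, , t]))  # sender = column
  rownames(k) <- net$channel_labels
  tt <- if (is.finite(net$fs) && !is.na(net$t0_index %||% NA))
    (seq_len(N) - 1 - net$t0_index) / net$fs else as.numeric(seq_len(N))
  structure(list(k = k, channel_labels = net$channel_labels, times = tt,
                 n_nodes = net$n_nodes, fs = net$fs,
                 t0_index = net$t0_index),
            class = "out_degree")
}

#' @export
print.out_degree <- function(x, ...) {
  cat(sprintf("<out_degree> %d nodes x %d time points; max out-degree %d\n",
              nrow(x$k), ncol(x$k), suppressWarnings(max(x$k, na.rm = TRUE))))
  invisible(x)
}

#' Plot the out-degree matrix as a node x time image
#' @param x An `out_degree` (or `binarized_out_degree`).
#' @param ... Passed to `image`.
#' @export
plot.out_degree <- function(x, ...) {
  m <- if (!is.null(x$b)) x$b else x$k
  image(x$times, seq_len(nrow(m)), t(m), xlab = "time rel. peak (s)",
        ylab = "", yaxt = "n", col = hcl.colors(16, "YlOrRd", rev = TRUE), ...)
  axis(2, at = seq_len(nrow(m)), labels = x$channel_labels, las = 2,
       cex.axis = 0.7)
  abline(v = 0, lty = 3)
  invisible(x)
}

#' Binarize the out-degree matrix
#'
#' With the default `"greater"` comparison, `b = 1` exactly where the
#' out-degree strictly exceeds the threshold (a threshold of three removes
#' interference from noise-level edges); `"greater_equal"` includes the
#' boundary value.
#'
#' @param k An `out_degree`.
#' @param threshold Non-negative integer. Default 3.
#' @param comparison `"greater"` (default) or `"greater_equal"`.
#' @return Object of class `binarized_out_degree` with matrix `b`.
#' @export
binarize_out_degree <- function(k, threshold = 3,
                                comparison = c("greater", "greater_equal")) {
  stopifnot(inherits(k, "out_degree"))
  comparison <- match.arg(comparison)
  if (threshold < 0) stop("threshold must be >= 0")
  b <- if (comparison == "greater") (k$k > threshold) + 0
       else (k$k >= threshold) + 0
  structure(list(b = b, threshold = threshold, comparison = comparison,
                 k = k$k, channel_labels = k$channel_labels,
                 times = k$times, n_nodes = k$n_nodes, fs = k$fs,
                 t0_index = k$t0_index),
            class = c("binarized_out_degree", "out_degree"))
}

#' Identify background-outflow channels
#'
#' A channel belongs to the background set when its binarized out-degree
#' is 1 in at least `min_fraction` of the baseline-window time points
#' (points without estimates are excluded from the denominator). The
#' baseline window defaults to the first second of the segment, well
#' before the discharge peak.
#'
#' @param b A `binarized_out_degree`.
#' @param baseline_window Length-2 integer vector of time indices
#'   (inclusive) into the columns of `b`, or `NULL` for the first second.
#' @param min_fraction Fraction of active baseline points required.
#'   Default 0.5.
#' @return Character vector of background channel labels (possibly empty),
#'   with the window used attached as attribute `baseline_window`.
#' @export
identify_background <- function(b, baseline_window = NULL,
                                min_fraction = 0.5) {
  stopifnot(inherits(b, "binarized_out_degree"))
  N <- ncol(b$b)
  if (is.null(baseline_window)) {
    n_base <- if (is.finite(b$fs)) as.integer(round(b$fs)) else max(1L, N %/% 6)
    baseline_window <- c(1L, min(n_base, N))
  }
  w <- baseline_window[1]:baseline_window[2]
  if (length(w) == 0L || any(w < 1L) || any(w > N))
    stop("baseline window empty or outside the segment")
  if (!is.na(b$t0_index %||% NA) && baseline_window[2] > b$t0_index)
    stop("baseline window must precede the discharge peak")
  frac <- apply(b$b[, w, drop = FALSE], 1, function(r) {
    val <- r[is.finite(r)]
    if (length(val) == 0L) 0 else mean(val)
  })
  bg <- b$channel_labels[frac >= min_fraction]
  attr(bg, "baseline_window") <- baseline_window
  attr(bg, "baseline_fraction") <- frac
  bg
}

# first index (within the searched range) at which `x` starts a run of at
# least `len` consecutive ones; NA treated as 0; returns c(onset, run_len)
# or NULL
.first_run <- function(x, from, len) {
  x <- ifelse(is.finite(x) & x == 1, 1, 0)
  n <- length(x)
  t <- from
  while (t <= n - len + 1) {
    if (all(x[t:(t + len - 1)] == 1)) {
      end <- t + len - 1
      while (end < n && x[end + 1] == 1) end <- end + 1
      return(c(onset = t, run_len = end - t + 1))
    }
    t <- t + 1
  }
  NULL
}

#' Localize the epileptogenic-zone electrode
#'
#' Scanning time forward from the end of the baseline window, the EZ
#' electrode is the first non-background channel whose binarized
#' out-degree stays 1 for at least `min_duration` consecutive points
#' (suppressing single-sample noise). Channels tying at the same onset are
#' reported in `ties` and broken by the longer sustained activation, then
#' by the larger total out-degree over that activation.
#'
#' @param b A `binarized_out_degree`.
#' @param background Character vector of background channel labels (from
#'   [identify_background()]), or `NULL` to compute it with defaults.
#' @param min_duration Minimum run length in samples. Default 2.
#' @param baseline_window Passed to [identify_background()] when
#'   `background` is `NULL`; also sets the scan start.
#' @return An object of class `ez_localization`: `electrode` (label, or
#'   `NA` with `localizable = FALSE` when no channel ever activates),
#'   `onset_index`, `onset_time_s`, `background`, `ties`.
#' @export
locate_ez <- function(b, background = NULL, min_duration = 2,
                      baseline_window = NULL) {
  stopifnot(inherits(b, "binarized_out_degree"))
  if (is.null(background))
    background <- identify_background(b, baseline_window)
  win <- if (!is.null(baseline_window)) baseline_window
         else attr(background, "baseline_window")
  if (is.null(win)) {
    N <- ncol(b$b)
    n_base <- if (is.finite(b$fs)) as.integer(round(b$fs)) else max(1L, N %/% 6)
    win <- c(1L, min(n_base, N))
  }
  from <- win[2] + 1L
  cand <- setdiff(b$channel_labels, background)
  if (length(cand) == 0L) stop("no non-background channel available")
  runs <- lapply(cand, function(ch)
    .first_run(b$b[ch, ], from, min_duration))
  names(runs) <- cand
  runs <- runs[!vapply(runs, is.null, TRUE)]
  if (length(runs) == 0L) {
    return(structure(list(electrode = NA_character_, onset_index = NA_integer_,
                          onset_time_s = NA_real_, localizable = FALSE,
                          background = as.character(background),
                          ties = character(0), runs = list(),
                          baseline_window = win),
                     class = "ez_localization"))
  }
  onsets <- vapply(runs, function(r) r["onset"], 0)
  earliest <- names(runs)[onsets == min(onsets)]
  ties <- character(0)
  winner <- earliest[1]
  if (length(earliest) > 1L) {
    ties <- earliest
    lens <- vapply(earliest, function(ch) runs[[ch]]["run_len"], 0)
    best <- earliest[lens == max(lens)]
    if (length(best) > 1L) {
      tot <- vapply(best, function(ch) {
        r <- runs[[ch]]
        sum(b$k[ch, r["onset"]:(r["onset"] + r["run_len"] - 1)], na.rm = TRUE)
      }, 0)
      best <- best[which.max(tot)]
    }
    winner <- best[1]
  }
  onset <- unname(runs[[winner]]["onset"])
  structure(list(electrode = winner, onset_index = onset,
                 onset_time_s = b$times[onset], localizable = TRUE,
                 background = as.character(background), ties = ties,
                 runs = runs, baseline_window = win),
            class = "ez_localization")
}

#' @export
print.ez_localization <- function(x, ...) {
  if (isTRUE(x$localizable)) {
    if (!is.null(x$onset_index))
      cat(sprintf("<ez_localization> electrode %s (onset index %d, %+.3f s rel. peak)\n",
                  x$electrode, x$onset_index, x$onset_time_s))
    else
      cat(sprintf("<ez_localization> electrode %s (%s of %d segments)\n",
                  x$electrode,
                  paste0(max(x$votes), "/", sum(x$votes), " votes"),
                  x$n_segments))
  } else cat("<ez_localization> not localizable (no sustained activation)\n")
  if (length(x$background))
    cat("  background channels:", paste(x$background, collapse = ", "), "\n")
  if (length(x$ties))
    cat("  co-earliest:", paste(x$ties, collapse = ", "), "\n")
  invisible(x)
}

#' Aggregate per-segment localizations for a patient
#'
#' Majority vote over the segment-level electrodes; non-localizable
#' segments abstain. Vote ties are reported in `ties` and resolved in the
#' spirit of the localization rule itself: among tied electrodes the one
#' with the earliest median onset (relative to the discharge peak) is
#' returned as `electrode`.
#'
#' @param results List of `ez_localization` objects.
#' @return An object of class `ez_localization` with `votes` attached.
#' @export
aggregate_patient <- function(results) {
  stopifnot(length(results) >= 1L)
  el <- vapply(results, function(r)
    if (isTRUE(r$localizable)) r$electrode else NA_character_, "")
  votes <- table(el[!is.na(el)])
  if (length(votes) == 0L) {
    return(structure(list(electrode = NA_character_, localizable = FALSE,
                          votes = votes, n_segments = length(results),
                          ties = character(0),
                          background = character(0)),
                     class = "ez_localization"))
  }
  top <- names(votes)[votes == max(votes)]
  ties <- if (length(top) > 1L) sort(top) else character(0)
  med_onset <- function(ch) {
    v <- vapply(results, function(r)
      if (isTRUE(r$localizable) && identical(r$electrode, ch))
        as.numeric(r$onset_time_s) else NA_real_, 0)
    stats::median(v, na.rm = TRUE)
  }
  onsets <- vapply(sort(top), med_onset, 0)
  winner <- names(onsets)[which.min(onsets)]
  structure(list(electrode = winner, localizable = TRUE,
                 onset_time_s = unname(onsets[winner]),
                 votes = votes, n_segments = length(results), ties = ties,
                 background = sort(unique(unlist(
                   lapply(results, `[[`, "background"))))),
            class = "ez_localization")
}
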