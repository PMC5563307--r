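# Adaptive directed transfer function: frequency-domain transform of the
# time-varying coefficients, receiver-normalized ADTF, band integration,
# and per-node total outflow.

.coeff_cube <- function(coeffs) {
  # accept a tvmvar fit, an M x (M p) x N array, or a [target, source,
  # lag, time] 4-d array (e.g. ground-truth coefficients)
  if (inherits(coeffs, "tvmvar")) return(coeffs$coeffs)
  a <- as.array(coeffs)
  if (length(dim(a)) == 4L) {
    d <- dim(a)
    return(array(a, dim = c(d[1], d[2] * d[3], d[4])))
  }
  if (length(dim(a)) == 3L) return(a)
  stop("coefficients must be a tvmvar fit or a 3-d/4-d array")
}

#' Frequency-domain transfer of time-varying MVAR coefficients
#'
#' Evaluates `A(f,t) = I - sum_{k=1}^p A_k(t) exp(-j 2 pi f dt k)` (the
#' lag-zero term is the identity, with lag coefficients entering
#' negatively, the convention under which `H = A^{-1}` is the MVAR
#' transfer matrix) and inverts it per frequency and time point.
#' Points where `A(f,t)` is singular or has reciprocal condition below
#' `1/cond_tol` are flagged unavailable (`NA`).
#'
#' @param model A `tvmvar` fit, or a coefficient array (either
#'   `[target, lag-blocked source, time]` or `[target, source, lag, time]`).
#' @param freqs Frequency grid in Hz, strictly increasing, within
#'   `(0, fs/2)`.
#' @param fs Sampling rate in Hz (taken from the fit if available).
#' @param cond_tol Condition-number threshold for flagging near-singular
#'   `A(f,t)`. Default 1e12.
#' @return A list of class `spectral_transfer`: `H` (complex array
#'   `[receiver, sender, frequency, time]`), `freqs`, `dt`.
#' @export
coeff_to_spectrum <- function(model, freqs, fs = NULL, cond_tol = 1e12) {
  cube <- .coeff_cube(model)
  if (is.null(fs)) fs <- if (inherits(model, "tvmvar")) model$fs else NA_real_
  if (!is.finite(fs)) stop("fs is required when the input carries no sampling rate")
  if (any(diff(freqs) <= 0)) stop("freqs must be strictly increasing")
  if (any(freqs <= 0 | freqs >= fs / 2))
    stop("freqs must lie strictly inside (0, fs/2)")
  M <- dim(cube)[1]; N <- dim(cube)[3]
  res <- adtf_cpp(cube, as.numeric(freqs), 1 / fs,
                  seq_along(freqs) - 1L, TRUE, TRUE, TRUE, 1 / cond_tol, 0L)
  H <- array(res$H, dim = c(M, M, length(freqs), N))
  labels <- if (inherits(model, "tvmvar")) model$channel_labels else NULL
  structure(list(H = H, freqs = as.numeric(freqs), dt = 1 / fs,
                 channel_labels = labels),
            class = "spectral_transfer")
}

#' Receiver-normalized ADTF from a spectral transfer
#'
#' `gamma2[i, j, f, t] = |H[i, j, f, t]|^2 / sum_m |H[i, m, f, t]|^2`:
#' the normalized directed flow from sender `j` to receiver `i`, lying in
#' `[0, 1]` with every receiver row summing to one over senders.
#'
#' @param st A `spectral_transfer`.
#' @return 4-d array `[receiver, sender, frequency, time]`.
#' @export
normalized_adtf <- function(st) {
  stopifnot(inherits(st, "spectral_transfer"))
  g <- abs(st$H)^2
  denom <- apply(g, c(1, 3, 4), sum)
  d <- dim(g)
  denom4 <- aperm(array(denom, dim = c(d[1], d[3], d[4], d[2])), c(1, 4, 2, 3))
  out <- g / denom4
  out[!is.finite(out)] <- NA_real_
  out
}

#' Band-integrated ADTF
#'
#' Averages the normalized ADTF over the grid frequencies inside the band
#' `[f1, f2]`. The divisor is the number of band bins, which keeps the
#' integrated value in `[0, 1]` on any grid (with a 1 Hz grid step this
#' coincides with dividing the bin sum by `f2 - f1`).
#'
#' @param gamma2 4-d array `[receiver, sender, frequency, time]`.
#' @param freqs Frequency grid matching dim 3 of `gamma2`.
#' @param band Length-2 numeric, band of interest in Hz. Default
#'   `c(0.5, 14.5)`.
#' @return 3-d array `Q2[receiver, sender, time]`.
#' @export
integrated_adtf <- function(gamma2, freqs, band = c(0.5, 14.5)) {
  sel <- which(freqs >= band[1] & freqs <= band[2])
  if (length(sel) == 0L) stop("no grid frequencies inside band [",
                              band[1], ", ", band[2], "] Hz")
  sub <- gamma2[, , sel, , drop = FALSE]
  apply(sub, c(1, 2, 4), mean)
}

#' Normalized total information outflow per node
#'
#' `outflow[j, t]` is the mean integrated ADTF from node `j` to every
#' other node: `sum_{k != j} Q2[k, j, t] / (n - 1)`.
#'
#' @param Q2 3-d array `[receiver, sender, time]` with `n >= 2` nodes.
#' @return Matrix `[node, time]` with values in `[0, 1]`.
#' @export
total_outflow <- function(Q2) {
  n <- dim(Q2)[1]
  if (is.na(n) || n < 2) stop("total outflow needs at least two nodes")
  sapply(seq_len(dim(Q2)[3]), function(t) {
    q <- Q2[, , t]
    (colSums(q) - diag(q)) / (n - 1)
  })
}

#' Time-varying ADTF connectivity of a fitted model
#'
#' One call from a `tvmvar` fit to the full dynamic connectivity set:
#' normalized ADTF on a frequency grid, band-integrated ADTF `Q2`, and
#' per-node total outflow. Time points without coefficient estimates (the
#' first `p` samples) carry `NA`. If the fitted segment carried filter
#' burn-in context, those leading samples are trimmed here, so the
#' connectivity grid is exactly the discharge-centred analysis epoch.
#'
#' @param model A `tvmvar` fit.
#' @param freqs Frequency grid in Hz. Default `seq(0.5, 15.5, by = 0.5)`.
#' @param band Band of interest in Hz for integration. Default
#'   `c(0.5, 14.5)`.
#' @param keep_gamma Keep the full `gamma2` array (memory for long
#'   grids). Default `TRUE`.
#' @param cond_tol Condition threshold for per-(f,t) inversion. Default 1e12.
#' @return An object of class `adtf_connectivity`: `Q2`
#'   (`[receiver, sender, time]`), `outflow` (`[node, time]`), `gamma2`
#'   (`[receiver, sender, frequency, time]`, if kept), `freqs`, `band`,
#'   `fs`, `t0_index`, `channel_labels`.
#' @export
adtf <- function(model, freqs = seq(0.5, 15.5, by = 0.5),
                 band = c(0.5, 14.5), keep_gamma = TRUE, cond_tol = 1e12) {
  stopifnot(inherits(model, "tvmvar"))
  if (!is.finite(model$fs)) stop("model carries no sampling rate")
  band_idx <- which(freqs >= band[1] & freqs <= band[2]) - 1L
  if (length(band_idx) == 0L) stop("no grid frequencies inside the band")
  burn0 <- model$burn_in %||% 0L
  res <- adtf_cpp(model$coeffs, as.numeric(freqs), 1 / model$fs,
                  as.integer(band_idx), keep_gamma, FALSE, TRUE, 1 / cond_tol,
                  as.integer(burn0))
  M <- model$n_channels; N <- model$n_samples
  lab <- model$channel_labels
  # drop any filter burn-in context so the connectivity grid is the
  # analysis epoch itself
  burn <- model$burn_in %||% 0L
  keep <- (burn + 1L):N
  Q2 <- res$Q2[, , keep, drop = FALSE]
  dimnames(Q2) <- list(lab, lab, NULL)
  outflow <- res$outflow[, keep, drop = FALSE]
  rownames(outflow) <- lab
  out <- list(Q2 = Q2, outflow = outflow, freqs = as.numeric(freqs),
              band = as.numeric(band), fs = model$fs,
              t0_index = model$t0_index - burn, n_nodes = M,
              first_valid = max(1L, model$first_valid - burn),
              channel_labels = lab)
  if (keep_gamma) {
    g <- array(res$gamma2, dim = c(M, M, length(freqs), N))
    g <- g[, , , keep, drop = FALSE]
    dimnames(g) <- list(lab, lab, NULL, NULL)
    out$gamma2 <- g
  }
  structure(out, class = "adtf_connectivity")
}

#' @export
print.adtf_connectivity <- function(x, ...) {
  cat(sprintf("<adtf_connectivity> %d nodes, %d time points, band %g-%g Hz (%d bins of %d-freq grid)\n",
              x$n_nodes, dim(x$Q2)[3], x$band[1], x$band[2],
              sum(x$freqs >= x$band[1] & x$freqs <= x$band[2]),
              length(x$freqs)))
  invisible(x)
}

#' Plot per-node total outflow over time
#' @param x An `adtf_connectivity`.
#' @param ... Passed to `matplot`.
#' @export
plot.adtf_connectivity <- function(x, ...) {
  N <- ncol(x$outflow)
  tt <- if (is.finite(x$fs) && !is.na(x$t0_index))
    (seq_len(N) - 1 - x$t0_index) / x$fs else seq_len(N)
  matplot(tt, t(x$outflow), type = "l", lty = 1,
          xlab = "time rel. peak (s)", ylab = "total outflow Q2", ...)
  abline(v = 0, lty = 3)
  legend("topleft", bty = "n", lty = 1, cex = 0.7,
         col = seq_len(nrow(x$outflow)), legend = x$channel_labels)
  invisible(x)
}

#' Export integrated ADTF (and outflow) as long-format tables
#'
#' @param conn An `adtf_connectivity`.
#' @return A list of two data.frames: `q2` with columns
#'   `time_s, sender, receiver, value` and `outflow` with
#'   `time_s, node, value`. `time_s` is relative to the discharge peak.
#' @export
connectivity_tables <- function(conn) {
  stopifnot(inherits(conn, "adtf_connectivity"))
  N <- dim(conn$Q2)[3]
  tt <- (seq_len(N) - 1 - (conn$t0_index %||% 0)) / conn$fs
  lab <- conn$channel_labels
  M <- conn$n_nodes
  grid <- expand.grid(receiver = seq_len(M), sender = seq_len(M),
                      t = seq_len(N))
  q2 <- data.frame(time_s = tt[grid$t], sender = lab[grid$sender],
                   receiver = lab[grid$receiver],
                   value = as.vector(conn$Q2))
  q2 <- q2[q2$sender != q2$receiver & is.finite(q2$value), , drop = FALSE]
  og <- expand.grid(node = seq_len(M), t = seq_len(N))
  ofl <- data.frame(time_s = tt[og$t], node = lab[og$node],
                    value = as.vector(conn$outflow))
  ofl <- ofl[is.finite(ofl$value), , drop = FALSE]
  list(q2 = q2, outflow = ofl)
}
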