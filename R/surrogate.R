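# Phase-randomization surrogates and the per-edge, per-time Gaussian null
# used to threshold the observed integrated ADTF into a binary dynamic
# network.

#' Phase-randomize a segment
#'
#' Per channel, independently: take the FFT, replace the phases of the
#' positive-frequency bins with independent uniform draws, enforce
#' conjugate symmetry, and invert. The amplitude spectrum of every
#' channel is preserved exactly while cross-channel phase structure — and
#' with it any causal interaction — is destroyed. DC and (for even
#' lengths) Nyquist bins keep their original real coefficients.
#'
#' Uses R's RNG, so results are reproducible under `set.seed()`.
#'
#' @param seg An `eeg_segment` or channels x samples matrix.
#' @return Object of the same type with phase-randomized channels.
#' @export
phase_randomize <- function(seg) {
  x <- .segment_matrix(seg)
  n <- ncol(x)
  half <- (n - 1) %/% 2                      # free positive-frequency bins
  out <- x
  for (i in seq_len(nrow(x))) {
    X <- fft(x[i, ])
    if (half > 0) {
      ph <- runif(half, 0, 2 * pi)
      idx <- 2:(half + 1)
      X[idx] <- Mod(X[idx]) * exp(1i * ph)
      X[n + 2 - idx] <- Conj(X[idx])
    }
    out[i, ] <- Re(fft(X, inverse = TRUE)) / n
  }
  if (inherits(seg, "eeg_segment")) {
    seg$data <- out
    seg
  } else out
}

#' Build the surrogate null distribution of integrated ADTF values
#'
#' Each surrogate is a phase-randomized copy of the segment passed through
#' the identical estimation chain as the observed data: Kalman fit at the
#' same order and update constant, ADTF on the same frequency band. The
#' per-(time, receiver, sender) mean and variance of the surrogate `Q2`
#' values — taken on the log scale, where the null distribution of the
#' integrated ADTF is close to Gaussian (on the raw scale it is strongly
#' right-skewed and a two-moment Gaussian summary miscalibrates the 1%
#' tail) — form the null used by [threshold_network()].
#'
#' Surrogates whose Kalman fit diverges are dropped and counted; if more
#' than 10% drop, the run fails.
#'
#' @param seg The observed (decimated) `eeg_segment`.
#' @param p Model order of the observed fit.
#' @param n_surrogates Number of surrogate replicates. Default 200.
#' @param uc Kalman update constant of the observed fit. Default 1e-3.
#' @param init Kalman initialization of the observed fit (`"ls"` or
#'   `"zero"`); surrogates reuse it so the null is matched. Default
#'   `"ls"`.
#' @param init_cov Initial state covariance scale of the observed fit.
#' @param freqs Frequency grid in Hz. Default `seq(0.5, 15.5, by = 0.5)`.
#' @param band Band of interest. Default `c(0.5, 14.5)`.
#' @param seed Optional RNG seed for exact reproducibility.
#' @return An object of class `surrogate_null`: `null_mean` and
#'   `null_var` (log-scale, `[receiver, sender, time]`), `n_surrogates`,
#'   `n_dropped`, `seed`, and the pipeline settings used.
#' @export
build_null <- function(seg, p, n_surrogates = 200, uc = 1e-3,
                       freqs = seq(0.5, 15.5, by = 0.5),
                       band = c(0.5, 14.5), seed = NULL,
                       init = c("ls", "zero"), init_cov = NULL) {
  init <- match.arg(init)
  stopifnot(inherits(seg, "eeg_segment"))
  if (!is.null(seed)) set.seed(seed)
  band_freqs <- freqs[freqs >= band[1] & freqs <= band[2]]
  if (length(band_freqs) == 0L) stop("no grid frequencies inside the band")
  M <- nrow(seg$data); Nfull <- ncol(seg$data)
  burn <- seg$burn_in %||% 0L
  keep_idx <- (burn + 1L):Nfull
  N <- length(keep_idx)
  s1 <- array(0, dim = c(M, M, N))
  s2 <- array(0, dim = c(M, M, N))
  kept <- 0L; dropped <- 0L
  for (r in seq_len(n_surrogates)) {
    sur <- phase_randomize(seg)
    q2 <- surrogate_q2_cpp(sur$data, as.integer(p), uc, band_freqs,
                           1 / seg$fs, init == "ls",
                           if (is.null(init_cov)) -1 else init_cov,
                           1e-2, burn)
    if (!any(is.finite(q2))) {               # diverged fit: all-NaN cube
      dropped <- dropped + 1L
      next
    }
    q2 <- q2[, , keep_idx, drop = FALSE]     # trim burn-in context
    lq <- log(q2 + 1e-3)                     # near-Gaussian null scale
    lq[!is.finite(lq)] <- 0                  # pre-estimate samples; masked below
    s1 <- s1 + lq
    s2 <- s2 + lq * lq
    kept <- kept + 1L
  }
  if (dropped > 0.1 * n_surrogates)
    stop("surrogate run failed: ", dropped, " of ", n_surrogates,
         " surrogate fits diverged")
  null_mean <- s1 / kept
  null_var <- pmax(s2 / kept - null_mean^2, 0)
  na_mask <- array(rep(seq_len(N) + burn < p + 1, each = M * M),
                   dim = c(M, M, N))
  null_mean[na_mask] <- NA_real_
  null_var[na_mask] <- NA_real_
  structure(list(null_mean = null_mean, null_var = null_var,
                 log_scale = TRUE, eps = 1e-3,
                 n_surrogates = kept, n_dropped = dropped, seed = seed,
                 order = p, uc = uc, init = init, freqs = freqs, band = band,
                 fs = seg$fs, channel_labels = seg$channel_labels),
            class = "surrogate_null")
}

#' @export
print.surrogate_null <- function(x, ...) {
  cat(sprintf("<surrogate_null> %d surrogates (%d dropped), order %d, band %g-%g Hz\n",
              x$n_surrogates, x$n_dropped, x$order, x$band[1], x$band[2]))
  invisible(x)
}

#' Threshold observed connectivity against the surrogate null
#'
#' An edge (sender j -> receiver i) at time t is declared present when
#' the observed `Q2` exceeds the upper-tail critical value of the
#' Gaussian surrogate null: `1 - pnorm((obs - mean)/sd) < alpha`,
#' one-sided, since only abnormally strong flow is of interest for
#' localization. The comparison is made on the scale on which the null
#' moments were taken (log scale by default, see [build_null()]). Cells
#' with zero null variance fall back to `obs > mean`. Self-edges are
#' forced absent. With `bonferroni = TRUE`, `alpha` is divided by the
#' number of off-diagonal edges.
#'
#' @param conn An `adtf_connectivity` (observed).
#' @param ens A `surrogate_null` built on the same segment and settings.
#' @param alpha Per-edge, per-time significance level. Default 0.01.
#' @param bonferroni Divide alpha by the edge count. Default `FALSE`.
#' @return An object of class `binary_dynamic_network`: `adj`
#'   (`[receiver, sender, time]`, 0/1 with `NA` before estimates exist),
#'   `alpha`, `n_nodes`, `channel_labels`, `fs`, `t0_index`.
#' @export
threshold_network <- function(conn, ens, alpha = 0.01, bonferroni = FALSE) {
  stopifnot(inherits(conn, "adtf_connectivity"),
            inherits(ens, "surrogate_null"))
  if (!all(dim(conn$Q2) == dim(ens$null_mean)))
    stop("observed connectivity and surrogate null are on different grids")
  M <- conn$n_nodes; N <- dim(conn$Q2)[3]
  a <- alpha
  if (bonferroni) a <- alpha / (M * (M - 1))
  obs <- if (isTRUE(ens$log_scale)) log(conn$Q2 + ens$eps) else conn$Q2
  sd0 <- sqrt(ens$null_var)
  z <- (obs - ens$null_mean) / sd0
  pval <- 1 - pnorm(z)
  adj <- array(NA_real_, dim = dim(conn$Q2))
  ok <- is.finite(pval)
  adj[ok] <- as.numeric(pval[ok] < a)
  zv <- is.finite(obs) & is.finite(ens$null_mean) & (sd0 == 0)
  adj[zv] <- as.numeric(obs[zv] > ens$null_mean[zv])
  for (t in seq_len(N)) {
    sl <- adj[, , t]
    if (any(is.finite(sl))) { diag(sl) <- 0; adj[, , t] <- sl }
  }
  dimnames(adj) <- list(conn$channel_labels, conn$channel_labels, NULL)
  structure(list(adj = adj, alpha = alpha, bonferroni = bonferroni,
                 n_nodes = M, channel_labels = conn$channel_labels,
                 fs = conn$fs, t0_index = conn$t0_index,
                 first_valid = conn$first_valid),
            class = "binary_dynamic_network")
}

#' @export
print.binary_dynamic_network <- function(x, ...) {
  n_t <- dim(x$adj)[3]
  present <- sum(x$adj == 1, na.rm = TRUE)
  cat(sprintf("<binary_dynamic_network> %d nodes x %d time points, alpha = %g, %d edges present\n",
              x$n_nodes, n_t, x$alpha, present))
  invisible(x)
}

#' Export a binary dynamic network as a long-format edge table
#'
#' @param net A `binary_dynamic_network`.
#' @return data.frame with columns `time_s, sender, receiver` listing the
#'   edges present at each time point.
#' @export
network_table <- function(net) {
  stopifnot(inherits(net, "binary_dynamic_network"))
  N <- dim(net$adj)[3]
  tt <- (seq_len(N) - 1 - (net$t0_index %||% 0)) / net$fs
  idx <- which(net$adj == 1, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(time_s = numeric(0), sender = character(0),
                      receiver = character(0)))
  df <- data.frame(time_s = tt[idx[, 3]],
                   sender = net$channel_labels[idx[, 2]],
                   receiver = net$channel_labels[idx[, 1]])
  df[order(df$time_s, df$sender, df$receiver), , drop = FALSE]
}
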