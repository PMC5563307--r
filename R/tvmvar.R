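# Time-varying MVAR: AIC order selection (stationary least-squares pre-fit)
# and Kalman-filter coefficient tracking.

.segment_matrix <- function(x) {
  if (inherits(x, "eeg_segment")) x$data
  else if (inherits(x, "eeg_recording")) x$data
  else as.matrix(x)
}

# Stationary multichannel least-squares VAR(p) fit, no intercept (signals
# are zero-mean after referencing/filtering). Returns coefficients with
# column m holding target channel m's lag-blocked coefficients, and the
# residual covariance chi = E'E / (N - p).
.var_ls <- function(x, p) {
  M <- nrow(x); N <- ncol(x)
  if (N <= p) stop("segment too short for order ", p)
  Y <- t(x[, (p + 1):N, drop = FALSE])
  Z <- matrix(0, N - p, M * p)
  for (k in seq_len(p))
    Z[, ((k - 1) * M + 1):(k * M)] <- t(x[, (p + 1 - k):(N - k), drop = FALSE])
  fit <- stats::lm.fit(Z, Y)
  # pivoted QR: a rank deficiency of p columns arises naturally from the
  # common-average reference (channels sum to zero), and the LS residuals
  # remain well-defined; anything worse is a genuinely singular regression
  if (fit$rank < M * p - p)
    stop("singular least-squares regression at order ", p)
  B <- as.matrix(fit$coefficients)
  B[is.na(B)] <- 0
  E <- as.matrix(fit$residuals)
  list(B = B, chi = crossprod(E) / (N - p))
}

#' Select the MVAR model order by AIC
#'
#' For each candidate order `p`, a stationary MVAR is fitted to the segment
#' by multichannel least squares and scored as
#' `AIC(p) = ln det(chi) + 2 M^2 p / N`, where `chi` is the residual
#' covariance, `M` the channel count and `N` the segment length. The
#' minimizing order is returned; ties go to the smaller order.
#'
#' Candidate orders are restricted to those with at least two observations
#' per regressor (`N - p >= 2 M p`): beyond that point the least-squares
#' problem approaches singularity, `ln det(chi)` collapses, and the score
#' degenerates. With 16 channels and 192-sample segments this caps the
#' usable range at p = 5 even when a nominal range up to 20 is requested.
#'
#' @param seg An `eeg_segment` (or channels x samples matrix).
#' @param p_min,p_max Nominal search range. Defaults 2 and 20.
#' @return An object of class `mvar_aic` with elements `scores` (named
#'   numeric, one per evaluated order), `selected`, `n_samples`,
#'   `n_channels`, and `residual_cov_by_order`.
#' @export
select_order <- function(seg, p_min = 2, p_max = 20) {
  x <- .segment_matrix(seg)
  # order describes the discharge epoch itself; drop any burn-in context
  if (inherits(seg, "eeg_segment") && (seg$burn_in %||% 0L) > 0L)
    x <- x[, -seq_len(seg$burn_in), drop = FALSE]
  M <- nrow(x); N <- ncol(x)
  p_feasible_max <- floor(N / (2 * M + 1))
  p_hi <- min(p_max, p_feasible_max)
  if (p_hi < p_min)
    stop("segment too short: ", N, " samples cannot support order ",
         p_min, " with ", M, " channels")
  orders <- p_min:p_hi
  scores <- numeric(length(orders))
  chis <- vector("list", length(orders))
  for (i in seq_along(orders)) {
    p <- orders[i]
    f <- .var_ls(x, p)
    # pseudo log-determinant: common-average-referenced EEG spans an
    # (M-1)-dimensional channel space, so chi carries one structural
    # near-zero eigenvalue; it is excluded consistently across orders.
    ev <- eigen(f$chi, symmetric = TRUE, only.values = TRUE)$values
    pos <- ev > max(ev) * 1e-10
    if (sum(!pos) > 1L || !any(pos))
      stop("singular residual covariance at order ", p)
    scores[i] <- sum(log(ev[pos])) + 2 * M^2 * p / N
    chis[[i]] <- f$chi
  }
  names(scores) <- orders
  names(chis) <- orders
  structure(list(scores = scores,
                 selected = orders[which.min(scores)],  # first min: smaller order on ties
                 n_samples = N, n_channels = M,
                 p_range_requested = c(p_min, p_max),
                 p_range_used = range(orders),
                 residual_cov_by_order = chis),
            class = "mvar_aic")
}

#' @export
print.mvar_aic <- function(x, ...) {
  cat(sprintf("<mvar_aic> selected order %d (searched %d..%d; %d channels, %d samples)\n",
              x$selected, x$p_range_used[1], x$p_range_used[2],
              x$n_channels, x$n_samples))
  print(round(x$scores, 3))
  invisible(x)
}

#' Fit a time-varying MVAR model by Kalman filtering
#'
#' Tracks the coefficients of `X(t) = sum_{i=1}^p A(i,t) X(t-i) + E(t)`
#' with a random-walk Kalman filter: the state is the set of coefficient
#' matrices, the state transition is the identity, and the process noise
#' covariance is `uc` times the current state covariance, so `uc` sets the
#' adaptation speed (larger tracks faster but noisier; the effective
#' tracking constant is about `1/sqrt(uc)` samples once the filter has
#' burned in). The first `p` samples serve only as regressors and carry no
#' estimates. The innovation covariance is tracked as an exponentially
#' weighted average (weight `uc`), which keeps it symmetric positive
#' semi-definite.
#'
#' Two initializations are available. `"zero"` starts the coefficients at
#' zero with identity state covariance — a neutral start appropriate for
#' long records, but on short segments the filter then spends roughly one
#' state dimension's worth of samples (`M^2 p / M`) re-identifying the
#' model, so persistent structure is invisible early on. `"ls"` (the
#' default) starts from the segment's stationary least-squares fit with a
#' small state covariance, so segment-wide structure is present from the
#' first tracked sample and the filter refines it; on a zero (or too
#' short) segment it falls back to the zero start.
#'
#' @param x An `eeg_segment` or channels x samples matrix.
#' @param order Model order `p` (positive integer).
#' @param uc Kalman update constant, in (0, 1). Default 1e-3.
#' @param init `"ls"` (stationary least-squares start, default) or
#'   `"zero"`.
#' @param init_cov Optional initial state covariance scale (diagonal);
#'   default: 1 for `"zero"`, `sqrt(uc)/p` for `"ls"` (near the steady-state
#'   gain, so the start is refined rather than discarded).
#' @return An object of class `tvmvar`: per-time coefficient estimates
#'   (`coeffs`, an M x (M p) x N array, rows = target channel, columns
#'   blocked by lag), `innovations` (M x N), `resid_cov` (M x M x N),
#'   `order`, `uc`, `fs`, `channel_labels`, and `first_valid` (= p + 1).
#' @export
tvmvar <- function(x, order, uc = 1e-3, init = c("ls", "zero"),
                   init_cov = NULL) {
  y <- .segment_matrix(x)
  init <- match.arg(init)
  M <- nrow(y); N <- ncol(y)
  order <- as.integer(order)
  if (order < 1L || N <= order) stop("need 1 <= order < n_samples")
  if (!(uc > 0 && uc < 1)) stop("uc must lie in (0, 1)")
  kf <- kalman_mvar_cpp(y, order, uc, init == "ls",
                        if (is.null(init_cov)) -1 else init_cov)
  if (kf$diverged_at > 0)
    stop("Kalman filter diverged (non-finite state) at time index ",
         kf$diverged_at)
  labels <- if (inherits(x, "eeg_segment")) x$channel_labels
            else rownames(y) %||% paste0("ch", seq_len(M))
  fs <- if (inherits(x, "eeg_segment")) x$fs else NA_real_
  t0 <- if (inherits(x, "eeg_segment")) x$t0_index else NA_integer_
  burn <- if (inherits(x, "eeg_segment")) x$burn_in %||% 0L else 0L
  structure(list(coeffs = kf$coeffs, innovations = kf$innovations,
                 resid_cov = kf$resid_cov, order = order, uc = uc, init = init,
                 fs = fs, t0_index = t0, burn_in = burn,
                 n_samples = N, n_channels = M,
                 channel_labels = labels, first_valid = order + 1L,
                 data = y),
            class = "tvmvar")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.tvmvar <- function(x, ...) {
  cat(sprintf("<tvmvar> order %d, %d channels, %d samples, uc = %g\n",
              x$order, x$n_channels, x$n_samples, x$uc))
  cat(sprintf("  estimates available for t = %d..%d\n",
              x$first_valid, x$n_samples))
  invisible(x)
}

#' Extract time-varying coefficient estimates
#'
#' @param object A `tvmvar` fit.
#' @param ... Unused.
#' @return A 4-d array `[target, source, lag, time]` with dimnames; the
#'   first `p` time slices are `NA`.
#' @export
coef.tvmvar <- function(object, ...) {
  M <- object$n_channels; p <- object$order; N <- object$n_samples
  a <- array(object$coeffs, dim = c(M, M, p, N),
             dimnames = list(object$channel_labels, object$channel_labels,
                             paste0("lag", seq_len(p)), NULL))
  a
}

#' @export
residuals.tvmvar <- function(object, ...) object$innovations

#' @export
fitted.tvmvar <- function(object, ...) object$data - object$innovations

#' One-step-ahead predictions from a time-varying MVAR fit
#'
#' Uses the coefficient estimate at each time point to predict that
#' sample from the preceding `p`; on `newdata`, the final coefficient
#' matrices of the fit are applied throughout.
#'
#' @param object A `tvmvar` fit.
#' @param newdata Optional channels x samples matrix.
#' @param ... Unused.
#' @return Matrix of one-step predictions (NA where no estimate exists).
#' @export
predict.tvmvar <- function(object, newdata = NULL, ...) {
  p <- object$order; M <- object$n_channels
  if (is.null(newdata)) return(fitted(object))
  y <- as.matrix(newdata)
  A <- object$coeffs[, , object$n_samples]          # final estimate
  out <- matrix(NA_real_, nrow(y), ncol(y))
  for (t in (p + 1):ncol(y)) {
    phi <- as.vector(y[, t - seq_len(p), drop = FALSE])
    out[, t] <- A %*% phi
  }
  out
}

#' @export
summary.tvmvar <- function(object, ...) {
  M <- object$n_channels; N <- object$n_samples
  half <- object$coeffs[, , max(object$first_valid, floor(N / 2)):N, drop = FALSE]
  Abar <- apply(half, c(1, 2), mean)
  innov <- object$innovations[, object$first_valid:N, drop = FALSE]
  out <- list(order = object$order, uc = object$uc,
              n_channels = M, n_samples = N,
              mean_coeffs_final_half = Abar,
              innovation_sd = apply(innov, 1, stats::sd),
              channel_labels = object$channel_labels)
  class(out) <- "summary.tvmvar"
  out
}

#' @export
print.summary.tvmvar <- function(x, ...) {
  cat(sprintf("Time-varying MVAR fit: order %d, uc = %g, %d channels x %d samples\n",
              x$order, x$uc, x$n_channels, x$n_samples))
  cat("Innovation SD per channel:\n")
  print(round(stats::setNames(x$innovation_sd, x$channel_labels), 4))
  cat("Mean coefficient matrix over the final half (lag-blocked columns):\n")
  print(round(x$mean_coeffs_final_half, 3))
  invisible(x)
}

#' Plot coefficient trajectories of a time-varying MVAR fit
#'
#' @param x A `tvmvar` fit.
#' @param pairs Matrix or data.frame with columns target, source, lag
#'   (indices); default: all lag-1 cross-channel pairs of the first two
#'   channels.
#' @param ... Passed to `matplot`.
#' @export
plot.tvmvar <- function(x, pairs = NULL, ...) {
  co <- coef(x)
  if (is.null(pairs))
    pairs <- cbind(target = c(1, 2), source = c(2, 1), lag = c(1, 1))
  pairs <- as.matrix(pairs)
  Y <- sapply(seq_len(nrow(pairs)), function(r)
    co[pairs[r, 1], pairs[r, 2], pairs[r, 3], ])
  tt <- if (is.finite(x$fs) && !is.na(x$t0_index))
    (seq_len(x$n_samples) - 1 - x$t0_index) / x$fs else seq_len(x$n_samples)
  matplot(tt, Y, type = "l", lty = 1,
          xlab = if (is.finite(x$fs)) "time rel. peak (s)" else "sample",
          ylab = "coefficient", ...)
  legend("topleft", bty = "n", lty = 1, col = seq_len(ncol(Y)),
         legend = apply(pairs, 1, function(r)
           sprintf("%s <- %s (lag %d)", x$channel_labels[r[1]],
                   x$channel_labels[r[2]], r[3])))
  invisible(x)
}

#' Simulate from a fitted time-varying MVAR
#'
#' Draws Gaussian innovations from the per-time estimated innovation
#' covariance and propagates them through the per-time coefficient
#' estimates (initial `p` samples copied from the fitted data).
#'
#' @param object A `tvmvar` fit.
#' @param nsim Number of replicate series. Default 1.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return A channels x samples matrix, or a list of them if `nsim > 1`.
#' @export
simulate.tvmvar <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  M <- object$n_channels; N <- object$n_samples; p <- object$order
  one <- function() {
    y <- matrix(0, M, N)
    y[, seq_len(p)] <- object$data[, seq_len(p), drop = FALSE]
    for (t in (p + 1):N) {
      A <- object$coeffs[, , t]
      Rt <- object$resid_cov[, , t]
      L <- tryCatch(chol(Rt), error = function(e) chol(Rt + diag(1e-10, M)))
      phi <- as.vector(y[, t - seq_len(p), drop = FALSE])
      y[, t] <- A %*% phi + drop(t(L) %*% rnorm(M))
    }
    rownames(y) <- object$channel_labels
    y
  }
  if (nsim == 1) one() else replicate(nsim, one(), simplify = FALSE)
}
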