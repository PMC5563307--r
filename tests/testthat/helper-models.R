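# shared helpers: small VAR systems with known structure, quick segments

# random stable VAR(p): diagonal oscillatory poles plus small random
# cross-coupling, rejection-sampled to spectral radius < 0.95
random_stable_var <- function(M, p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    A <- array(rnorm(M * M * p, sd = 0.15), dim = c(M, M, p))
    for (m in seq_len(M)) {
      r <- runif(1, 0.5, 0.85); th <- runif(1, 0.2, 2.5)
      A[m, m, 1] <- 2 * r * cos(th) * 0.5
      if (p >= 2) A[m, m, 2] <- -r^2 * 0.5
    }
    if (var_spectral_radius(A) < 0.95) return(A)
  }
}

# simulate a stationary VAR(p) directly (channels x n), unit-variance noise
simulate_var <- function(A, n, sd = 1, seed = NULL, burn = 200) {
  if (!is.null(seed)) set.seed(seed)
  M <- dim(A)[1]; p <- dim(A)[3]
  ntot <- n + burn
  y <- matrix(0, M, ntot)
  for (t in (p + 1):ntot) {
    acc <- rnorm(M, sd = sd)
    for (k in seq_len(p)) acc <- acc + A[, , k] %*% y[, t - k]
    y[, t] <- acc
  }
  y[, (burn + 1):ntot, drop = FALSE]
}

# wrap a plain matrix as a segment at a given rate
as_segment <- function(y, fs = 32, t0 = ncol(y) %/% 2) {
  eeg_segment(y, fs, t0_index = t0)
}

# expand a time-constant coefficient array [M, M, p] to the 4-d
# [target, source, lag, time] layout that coeff_to_spectrum accepts
constant_coeffs <- function(A, n_time) {
  d <- dim(A)
  array(A, dim = c(d[1], d[2], d[3], n_time))
}
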