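test_that("scalar transfer function matches the closed form for AR(1)", {
  a <- 0.5; fs <- 32
  co <- constant_coeffs(array(a, dim = c(1, 1, 1)), 4)
  st <- coeff_to_spectrum(co, freqs = c(1, 8, 15), fs = fs)
  for (k in 1:3) {
    f <- c(1, 8, 15)[k]
    expected <- 1 / abs(1 - a * exp(-2i * pi * f / fs))^2
    expect_equal(abs(st$H[1, 1, k, 2])^2, expected, tolerance = 1e-12)
  }
  # zero coefficient: identity transfer at every frequency
  st0 <- coeff_to_spectrum(constant_coeffs(array(0, c(1, 1, 1)), 2),
                           freqs = c(2, 10), fs = fs)
  expect_equal(abs(st0$H[1, 1, , ]), matrix(1, 2, 2))
})

test_that("diagonal models give diagonal H and an identity gamma2 pattern", {
  A <- array(0, dim = c(3, 3, 2))
  diag(A[, , 1]) <- c(0.5, 0.3, -0.2); diag(A[, , 2]) <- 0.2
  st <- coeff_to_spectrum(constant_coeffs(A, 3), freqs = c(1, 5, 10), fs = 32)
  g <- normalized_adtf(st)
  for (t in 1:3) for (f in 1:3) {
    H <- st$H[, , f, t]
    expect_lt(max(abs(H[upper.tri(H)]), abs(H[lower.tri(H)])), 1e-14)
    expect_equal(g[, , f, t], diag(3), tolerance = 1e-12)
  }
})

test_that("gamma2 rows sum to one on random stable models", {
  for (r in 1:25) {
    A <- random_stable_var(3, 2, seed = 900 + r)
    st <- coeff_to_spectrum(constant_coeffs(A, 2),
                            freqs = seq(0.5, 15.5, 0.5), fs = 32)
    g <- normalized_adtf(st)
    sums <- apply(g, c(1, 3, 4), sum)
    expect_lt(max(abs(sums - 1)), 1e-10)
    expect_true(all(g >= 0 & g <= 1))
  }
})

test_that("equal |H| entries split gamma2 evenly", {
  H <- array(0 + 0i, dim = c(2, 2, 1, 1))
  H[1, 1, 1, 1] <- 1
  H[2, 1, 1, 1] <- 0.3 + 0.4i          # |.|  = 0.5
  H[2, 2, 1, 1] <- 0.5
  st <- structure(list(H = H, freqs = 1, dt = 1 / 32), class = "spectral_transfer")
  g <- normalized_adtf(st)
  expect_equal(g[2, 1, 1, 1], 0.5)
  expect_equal(g[2, 2, 1, 1], 0.5)
})

test_that("band integration averages bins and agrees with f2-f1 on a 1 Hz grid", {
  freqs <- seq(0.5, 15.5, 0.5)
  g <- array(0.25, dim = c(2, 2, length(freqs), 3))
  Q <- integrated_adtf(g, freqs, band = c(0.5, 14.5))
  expect_equal(Q, array(0.25, dim = c(2, 2, 3)))   # mean of a constant

  # diagonal-only gamma2 integrates to the identity pattern
  gd <- array(0, dim = c(3, 3, length(freqs), 2))
  for (i in 1:3) gd[i, i, , ] <- 1
  Qd <- integrated_adtf(gd, freqs, c(0.5, 14.5))
  expect_equal(Qd[, , 1], diag(3))

  # on an integer grid the bin-count divisor and the literal f2 - f1
  # divisor agree to within one part in the bin count
  f1hz <- 1:15
  set.seed(18)
  g1 <- array(runif(2 * 2 * 15 * 2), dim = c(2, 2, 15, 2))
  band <- c(1, 15)
  nb <- sum(f1hz >= band[1] & f1hz <= band[2])           # 15 bins
  bin_mean <- integrated_adtf(g1, f1hz, band)
  literal <- apply(g1, c(1, 2, 4), sum) / (band[2] - band[1])
  expect_equal(bin_mean, literal * (band[2] - band[1]) / nb,
               tolerance = 1e-12)
  expect_lt(max(abs(bin_mean / literal - 1)), 1 / (nb - 1))
  expect_error(integrated_adtf(g1, f1hz, c(20, 25)), "grid")
})

test_that("total outflow is the off-diagonal column mean", {
  Q <- array(0, dim = c(3, 3, 2))
  Q[2, 1, 1] <- 0.4; Q[3, 1, 1] <- 0.2
  out <- total_outflow(Q)
  expect_equal(out[1, 1], 0.3)
  expect_equal(out[2, 1], 0)
  expect_equal(out[, 2], rep(0, 3))
  expect_error(total_outflow(array(0, c(1, 1, 2))), "two nodes")
})

test_that("cross-block connectivity of a block-diagonal model is exactly zero", {
  A <- array(0, dim = c(4, 4, 2))
  A[1:2, 1:2, 1] <- matrix(c(0.5, 0.3, 0.2, 0.4), 2, 2)
  A[3:4, 3:4, 1] <- matrix(c(0.3, -0.2, 0.25, 0.5), 2, 2)
  A[1:2, 1:2, 2] <- diag(0.1, 2)
  expect_lt(var_spectral_radius(A), 1)
  st <- coeff_to_spectrum(constant_coeffs(A, 2), freqs = seq(1, 15), fs = 32)
  g <- normalized_adtf(st)
  Q <- integrated_adtf(g, seq(1, 15), c(1, 14))
  cross <- c(Q[1:2, 3:4, ], Q[3:4, 1:2, ])
  expect_lt(max(abs(cross)), 1e-24)
})

test_that("a simulated driver has the largest outflow during coupling", {
  A <- array(0, dim = c(3, 3, 1))
  diag(A[, , 1]) <- 0.5
  A[2, 1, 1] <- 0.45; A[3, 1, 1] <- 0.45
  y <- simulate_var(A, 600, seed = 19)
  fit <- tvmvar(as_segment(y), 1, uc = 0.01)
  conn <- adtf(fit, freqs = seq(0.5, 15.5, 0.5), keep_gamma = FALSE)
  late <- 300:600
  ofl <- rowMeans(conn$outflow[, late])
  expect_gt(ofl[1], ofl[2])
  expect_gt(ofl[1], ofl[3])
})

test_that("time-resolved ADTF converges to the true-coefficient DTF", {
  A <- array(c(0.5, 0.4, 0, 0.3), dim = c(2, 2, 1))   # 1 -> 2 coupling
  y <- simulate_var(A, 2000, seed = 20)
  fit <- tvmvar(as_segment(y), 1, uc = 1e-3)
  freqs <- seq(0.5, 15.5, 0.5)
  conn <- adtf(fit, freqs = freqs, keep_gamma = TRUE)
  g_true <- normalized_adtf(coeff_to_spectrum(constant_coeffs(A, 1),
                                              freqs = freqs, fs = 32))
  est <- apply(conn$gamma2[, , , 1000:2000], c(1, 2, 3), mean)
  expect_lt(max(abs(est - g_true[, , , 1])), 0.1)
})

test_that("connectivity carries no values before estimates exist", {
  y <- simulate_var(random_stable_var(2, 2, seed = 3), 100)
  fit <- tvmvar(as_segment(y), 2, uc = 0.01)
  conn <- adtf(fit, keep_gamma = FALSE)
  expect_true(all(is.na(conn$Q2[, , 1:2])))
  expect_true(all(is.finite(conn$Q2[, , 3:100])))
})
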