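test_that("stability validation rejects unstable schedules", {
  A <- array(0, dim = c(2, 2, 1))
  diag(A[, , 1]) <- 1.05
  expect_gt(var_spectral_radius(A), 1)
  expect_error(sim_config(n_channels = 2, base_tensor = A, duration = 10),
               "unstable")
  ok <- sim_config(n_channels = 2,
                   base_tensor = array(c(0.5, 0, 0, 0.5), c(2, 2, 1)),
                   duration = 10)
  expect_s3_class(ok, "sim_config")
})

test_that("decoupled channels come out independent", {
  cfg <- sim_config(n_channels = 4, duration = 20, fs = 256,
                    base_tensor = array(0, dim = c(4, 4, 2)), seed = 31)
  y <- simulate_tv_mvar(cfg)$recording$data[, 1:5000]
  cc <- cor(t(y))
  lag1 <- cor(t(y[, -1]), t(y[, -5000]))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.1)
  expect_lt(max(abs(lag1[row(lag1) != col(lag1)])), 0.1)
})

test_that("stationary AR(1) reproduces the Yule-Walker variance", {
  cfg <- sim_config(n_channels = 1, duration = 40, fs = 256, noise_sd = 1,
                    base_tensor = array(0.5, dim = c(1, 1, 1)), seed = 32)
  y <- simulate_tv_mvar(cfg)$recording$data
  expect_lt(abs(var(y[1, -(1:200)]) - 1 / (1 - 0.25)) / (1 / (1 - 0.25)), 0.1)
})

test_that("simulation is bit-identical under a fixed seed, files included", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- make_fixture("two_channel_driver", seed = 5, dir = d1)
  f2 <- make_fixture("two_channel_driver", seed = 5, dir = d2)
  expect_identical(readBin(f1$edf, "raw", file.size(f1$edf)),
                   readBin(f2$edf, "raw", file.size(f2$edf)))
  expect_identical(readLines(f1$events), readLines(f2$events))
})

test_that("spike injection places propagated templates where expected", {
  cfg <- sim_config(n_channels = 3, duration = 14, fs = 256, noise_sd = 1e-6,
                    base_tensor = array(0, dim = c(3, 3, 2)),
                    source_channel = "ch1", source_targets = "ch2",
                    coupling = 0, spike_times = 7, spike_amp = 100,
                    prop_delay_ms = 20, attenuation = 0.5, seed = 33)
  rec0 <- simulate_tv_mvar(cfg)$recording
  rec <- inject_spikes(rec0, cfg)
  # zero-amplitude template leaves the recording unchanged
  cfg0 <- cfg; cfg0$spike_amp <- 0
  expect_identical(inject_spikes(rec0, cfg0)$data, rec0$data)
  # the labeled peak sample carries baseline + the template maximum on
  # the source, and the same (attenuated) value on a target after its
  # propagation delay
  tpl <- adtfnet:::.spike_template(256, 100, cfg$spike_ms, cfg$wave_ms)
  pk <- round(7 * 256)                             # 0-based labeled peak
  expect_equal(rec$data[1, pk + 1],
               rec0$data[1, pk + 1] + max(tpl$w), tolerance = 1e-6)
  # ch2 is a coupled target: its template arrives after its propagation
  # lag; ch3 is not coupled and uses the base delay
  d2 <- cfg$coupling_lag[1]
  expect_equal(rec$data[2, pk + d2 + 1],
               rec0$data[2, pk + d2 + 1] + 0.5 * max(tpl$w),
               tolerance = 1e-6)
  d3 <- round((20 + 0.25 * 3) * 256 / 1000)
  expect_equal(rec$data[3, pk + d3 + 1],
               rec0$data[3, pk + d3 + 1] + 0.5 * max(tpl$w),
               tolerance = 1e-6)
})

test_that("fixture presets write self-contained datasets", {
  d <- withr::local_tempdir()
  fx <- make_fixture("null_independent", seed = 2, dir = d)
  expect_true(file.exists(fx$edf))
  expect_true(file.exists(fx$events))
  tr <- jsonlite::fromJSON(fx$truth_json)
  expect_identical(tr$preset, "null_independent")
  rec <- read_edf(fx$edf)
  expect_equal(nrow(rec$data), 16)
  expect_equal(rec$fs, 256)
  ev <- read_events(fx$events, recording_duration(rec))
  expect_gt(nrow(ev), 0)
  expect_error(make_fixture("no_such_preset", seed = 1, dir = d))
})

test_that("the planted-source fixture honours its documented structure", {
  d <- withr::local_tempdir()
  fx <- make_fixture("full16_planted_source", seed = 4, dir = d)
  tr <- jsonlite::fromJSON(fx$truth_json)
  expect_identical(tr$source_channel, "F7")
  expect_gte(length(tr$source_targets), 4)
  expect_gte(length(tr$spike_times_s), 5)
  expect_equal(tr$coupling_windows_s$from_s, tr$spike_times_s - 0.5)
  rec <- read_edf(fx$edf)
  expect_identical(rec$channel_labels, standard_1020_labels())
})
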