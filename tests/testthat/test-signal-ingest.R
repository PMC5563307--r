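test_that("EDF round trip preserves labels, rate and signal to 16-bit accuracy", {
  set.seed(7)
  amp <- 50
  rec <- eeg_recording(matrix(rnorm(16 * 512, sd = amp), 16, 512), 256,
                       standard_1020_labels())
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_identical(back$channel_labels, standard_1020_labels())
  expect_equal(back$fs, 256)
  # 16-bit quantization over the per-channel physical range
  expect_lt(max(abs(back$data - rec$data)), amp * 12 / 65536)
})

test_that("read_edf selects channels by label and rejects unknown labels", {
  set.seed(8)
  labels <- c(standard_1020_labels(), "ECG", "EMG")
  rec <- eeg_recording(matrix(rnorm(18 * 256), 18, 256), 256, labels)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  sel <- read_edf(path, channels = standard_1020_labels())
  expect_identical(sel$channel_labels, standard_1020_labels())
  expect_equal(nrow(sel$data), 16)
  expect_error(read_edf(path, channels = c("Fp1", "XX")), "not present")
  expect_error(read_edf("no/such/file.edf"), "cannot read")
})

test_that("event reading applies the 3-s margin rule and flags bad rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("peak_time_s,label", "55.2,spike", "10.0,spike"), path)
  ev <- read_events(path, duration = 120)
  expect_equal(ev$peak_time_s, c(10.0, 55.2))   # sorted ascending

  writeLines(c("peak_time_s", "1.0", "118.5", "60"), path)
  expect_warning(ev2 <- read_events(path, duration = 120), "dropped")
  expect_equal(ev2$peak_time_s, 60)

  writeLines(c("peak_time_s", "abc"), path)
  expect_error(read_events(path, duration = 120), "line")

  writeLines("peak_time_s", path)
  expect_warning(ev3 <- read_events(path, duration = 120), "no events")
  expect_equal(nrow(ev3), 0L)
})

test_that("average reference zeroes the per-sample channel mean", {
  rec <- eeg_recording(matrix(c(1, 3), 2, 1), 100)
  expect_equal(average_reference(rec)$data[, 1], c(Fp1 = -1, Fp2 = 1),
               ignore_attr = TRUE)
  set.seed(9)
  rec <- eeg_recording(matrix(rnorm(16 * 1000, sd = 30), 16, 1000), 256)
  out <- average_reference(rec)
  expect_lt(max(abs(colMeans(out$data))), 1e-10)
  cst <- eeg_recording(matrix(5, 3, 10), 10)
  expect_true(all(average_reference(cst)$data == 0))
  expect_error(average_reference(eeg_recording(matrix(1, 1, 10), 10)),
               "two channels")
})

test_that("band-pass passes in-band and attenuates out-of-band sinusoids", {
  fs <- 256; tt <- seq(0, 4, by = 1 / fs)[-1]
  rms <- function(x) sqrt(mean(x^2))
  for (case in list(c(f = 50, keep = FALSE), c(f = 10, keep = TRUE))) {
    x <- sin(2 * pi * case[["f"]] * tt)
    rec <- eeg_recording(matrix(x, 2, length(x), byrow = TRUE), fs)
    out <- bandpass_filter(rec, 0.5, 30)
    # ignore filter edge transients
    core <- out$data[1, 200:(length(tt) - 200)]
    if (case[["keep"]]) expect_gt(rms(core), 0.95 * rms(x))
    else expect_lt(rms(core), 0.05 * rms(x))
  }
  z <- eeg_recording(matrix(0, 2, 1024), 256)
  expect_equal(bandpass_filter(z)$data, z$data)
  expect_error(bandpass_filter(eeg_recording(matrix(1, 2, 64), 256),
                               0.5, 200), "fs/2")
})

test_that("segment extraction uses half-open windows with the peak at 3 s", {
  set.seed(10)
  rec <- eeg_recording(matrix(rnorm(2 * 256 * 20), 2, 256 * 20), 256)
  ev <- discharge_events(10.0)
  segs <- extract_segments(rec, ev)
  expect_length(segs, 1)
  s <- segs[[1]]
  expect_equal(ncol(s$data), 1536)
  expect_equal(s$t0_index, 768)
  # half-open [1792, 3328): 0-based sample 1792 is column 1793
  expect_equal(s$data[, 1], rec$data[, 1793])
  expect_equal(s$data[, 1536], rec$data[, 3328])

  expect_length(extract_segments(rec, discharge_events(numeric(0))), 0)
  three <- extract_segments(rec, discharge_events(c(5, 10, 15)))
  expect_length(three, 3)
  expect_equal(vapply(three, function(x) x$event$peak_time_s, 0), c(5, 10, 15))
})

test_that("decimation divides rate, length and peak index; filters aliases", {
  set.seed(11)
  seg <- eeg_segment(matrix(rnorm(2 * 1536), 2, 1536), 256, t0_index = 768)
  dec <- decimate_segment(seg, 8)
  expect_equal(ncol(dec$data), 192)
  expect_equal(dec$fs, 32)
  expect_equal(dec$t0_index, 96)
  expect_identical(decimate_segment(seg, 1), seg)
  expect_error(decimate_segment(eeg_segment(matrix(0, 1, 100), 256, 50), 8),
               "divisible")

  # 20 Hz sinusoid is above the post-decimation Nyquist (16 Hz): its
  # aliased power must be almost entirely removed
  tt <- seq_len(1536) / 256
  x <- sin(2 * pi * 20 * tt)
  s2 <- eeg_segment(rbind(x, x), 256, t0_index = 768)
  d2 <- decimate_segment(s2, 8)
  expect_lt(mean(d2$data[1, ]^2), 0.05 * mean(x^2))
})

test_that("preprocessing is linear: scaling input scales segments", {
  set.seed(12)
  rec <- eeg_recording(matrix(rnorm(4 * 256 * 10), 4, 256 * 10), 256)
  ev <- discharge_events(5)
  s1 <- preprocess_segments(rec, ev)[[1]]
  rec2 <- rec; rec2$data <- 3.7 * rec$data
  s2 <- preprocess_segments(rec2, ev)[[1]]
  expect_equal(s2$data, 3.7 * s1$data, tolerance = 1e-6)
})
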