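# Synthetic EEG: piecewise-stationary time-varying MVAR signals with a
# planted discharge source, spike-and-wave transients, and ground-truth
# connectivity, so every pipeline stage can be validated without clinical
# recordings.

#' Companion-matrix spectral radius of a VAR coefficient tensor
#'
#' @param A Array `[target, source, lag]`.
#' @return The spectral radius; the process is stable iff it is < 1.
#' @export
var_spectral_radius <- function(A) {
  d <- dim(A)
  M <- d[1]; p <- d[3]
  comp <- matrix(0, M * p, M * p)
  for (k in seq_len(p)) comp[1:M, ((k - 1) * M + 1):(k * M)] <- A[, , k]
  if (p > 1)
    comp[(M + 1):(M * p), 1:(M * (p - 1))] <- diag(M * (p - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

# oscillatory AR(2) block: pole radius r at frequency f0 (Hz) given fs
.ar2_poles <- function(r, f0, fs) {
  th <- 2 * pi * f0 / fs
  c(2 * r * cos(th), -r^2)
}

#' Simulation configuration for synthetic discharge EEG
#'
#' Defines a piecewise-stationary MVAR generator: every channel carries a
#' stable oscillatory AR(2) baseline (pole radius `ar_r` at `ar_f0` Hz);
#' `background_sources` channels additionally send permanent directed
#' coupling to their targets; the `source_channel` sends coupling to
#' `source_targets` only during a window from `coupling_lead` s before
#' each spike peak until `coupling_tail` s after it — emulating an
#' epileptogenic zone that activates prior to the discharge and then
#' propagates. Spike-and-wave transients are added on top by
#' [inject_spikes()]. Every scheduled coefficient tensor is checked for
#' stability (companion spectral radius < 1); because the coupling graph
#' is acyclic, coupling does not move the poles.
#'
#' @param n_channels Number of channels. Default 16 (10-20 labels).
#' @param channel_labels Montage labels. Default [standard_1020_labels()].
#' @param fs Sampling rate in Hz. Default 256.
#' @param duration Recording length in seconds.
#' @param ar_r,ar_f0 Baseline AR(2) pole radius and frequency (Hz).
#'   Defaults 0.9 and 6 (an in-band theta-range rhythm).
#' @param noise_sd Innovation standard deviation, microvolts. Default 10.
#' @param base_tensor Optional explicit `[M, M, lag]` coefficient tensor
#'   overriding the AR(2)-plus-background construction (for bespoke test
#'   systems).
#' @param source_channel Label of the planted discharge source, or `NULL`.
#' @param source_targets Labels receiving the source's coupling.
#' @param coupling Source coupling coefficient. Default 0.5.
#' @param coupling_lag Coupling lag in samples at `fs`. Default 24
#'   (~94 ms at 256 Hz, three samples after factor-8 decimation, clear of
#'   the anti-alias filter's temporal smear).
#' @param spike_times Spike peak times in seconds (each >= 3 s from the
#'   recording edges).
#' @param coupling_lead Seconds the source coupling switches on before
#'   each spike peak. Default 0.5.
#' @param coupling_tail Seconds it stays on after the peak. Default 1.5.
#' @param spike_amp Spike template peak amplitude, microvolts. Default 100.
#' @param spike_ms,wave_ms Sharp-peak and slow-wave widths, ms. Defaults
#'   70 and 200.
#' @param prop_delay_ms Base propagation delay to non-source channels, ms;
#'   channel k receives the template after `prop_delay_ms + 0.25 * k` ms
#'   (a sub-sample spread at the 32 Hz analysis rate). Default 90.
#' @param attenuation Template amplitude factor on non-source channels.
#'   Default 0.75.
#' @param background_sources Named list: background channel label ->
#'   character vector of its permanent coupling targets.
#' @param background_coupling Background coupling coefficient. Default 0.5.
#' @param seed RNG seed (required for reproducibility).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_channels = 16,
                       channel_labels = if (n_channels == 16)
                         standard_1020_labels() else
                           paste0("ch", seq_len(n_channels)),
                       fs = 256, duration = 40,
                       ar_r = 0.9, ar_f0 = 6, noise_sd = 10,
                       base_tensor = NULL,
                       source_channel = NULL, source_targets = character(0),
                       coupling = 0.5, coupling_lag = 24,
                       spike_times = numeric(0),
                       coupling_lead = 0.5, coupling_tail = 1.5,
                       spike_amp = 100, spike_ms = 70, wave_ms = 200,
                       prop_delay_ms = 90, attenuation = 0.75,
                       background_sources = list(),
                       background_coupling = 0.5,
                       seed = 1) {
  M <- n_channels
  stopifnot(length(channel_labels) == M)
  if (length(spike_times) &&
      (min(spike_times) < 3 || max(spike_times) > duration - 3))
    stop("spike times must respect the 3-s margins of the recording")

  p <- if (!is.null(base_tensor)) dim(base_tensor)[3]
       else max(2L, as.integer(max(coupling_lag)) + 2L)
  ar <- .ar2_poles(ar_r, ar_f0, fs)
  # additive signal mixing: the target's output gains b * source(t - d)
  # without passing through the target's resonant AR recursion, realized
  # by AR-compensated coefficients at lags d, d+1, d+2 (the target's own
  # AR polynomial applied to the injected copy)
  # d may be a vector: one propagation lag per target (staggered delays
  # keep the targets'"'"' received copies at distinct lags, so the directed
  # structure is identifiable per target rather than collapsing onto a
  # single representative)
  mix_in <- function(A, targets, source_idx, b, d) {
    d <- rep_len(d, length(targets))
    for (ii in seq_along(targets)) {
      ti <- targets[ii]; di <- d[ii]
      A[ti, source_idx, di] <- A[ti, source_idx, di] + b
      A[ti, source_idx, di + 1] <- A[ti, source_idx, di + 1] - b * ar[1]
      A[ti, source_idx, di + 2] <- A[ti, source_idx, di + 2] - b * ar[2]
    }
    A
  }
  if (is.null(base_tensor)) {
    A0 <- array(0, dim = c(M, M, p))
    for (m in seq_len(M)) { A0[m, m, 1] <- ar[1]; A0[m, m, 2] <- ar[2] }
    for (bs in names(background_sources)) {
      j <- match(bs, channel_labels)
      ti <- match(background_sources[[bs]], channel_labels)
      if (anyNA(c(j, ti))) stop("unknown background channel label")
      A0 <- mix_in(A0, ti, j, background_coupling, coupling_lag[1])
    }
  } else {
    A0 <- base_tensor
    stopifnot(all(dim(A0)[1:2] == M))
  }

  Acoupled <- A0
  src <- NULL
  if (!is.null(source_channel)) {
    src <- match(source_channel, channel_labels)
    ti <- match(source_targets, channel_labels)
    if (anyNA(c(src, ti))) stop("unknown source/target channel label")
    if (is.null(base_tensor)) {
      Acoupled <- mix_in(Acoupled, ti, src, coupling, coupling_lag)
    } else {
      Acoupled[ti, src, min(coupling_lag[1], p)] <- coupling
    }
  }

  for (nm in c("base", "coupled")) {
    A <- if (nm == "base") A0 else Acoupled
    r <- var_spectral_radius(A)
    if (r >= 1)
      stop("unstable coefficient tensor (", nm,
           " regime): companion spectral radius ", round(r, 4))
  }

  structure(list(n_channels = M, channel_labels = channel_labels, fs = fs,
                 duration = duration, order = p, base_tensor = A0,
                 coupled_tensor = Acoupled, noise_sd = noise_sd,
                 source_channel = source_channel,
                 source_targets = source_targets, coupling = coupling,
                 coupling_lag = coupling_lag, spike_times = spike_times,
                 coupling_lead = coupling_lead,
                 coupling_tail = coupling_tail, spike_amp = spike_amp,
                 spike_ms = spike_ms, wave_ms = wave_ms,
                 prop_delay_ms = prop_delay_ms, attenuation = attenuation,
                 background_sources = background_sources,
                 background_coupling = background_coupling, seed = seed),
            class = "sim_config")
}

#' Simulate a recording from the piecewise-stationary MVAR schedule
#'
#' Generates sample by sample from the regime active at each time: the
#' coupled tensor inside each `[spike - coupling_lead, spike +
#' coupling_tail]` window, the base tensor elsewhere. Innovations are
#' i.i.d. Gaussian. Deterministic under the config's seed.
#'
#' @param cfg A `sim_config`.
#' @return List with `recording` (an `eeg_recording`) and `truth` (class
#'   `sim_truth`: source, targets, coupling windows, background map,
#'   spike times).
#' @export
simulate_tv_mvar <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  M <- cfg$n_channels; p <- cfg$order
  N <- as.integer(round(cfg$duration * cfg$fs))
  Abase <- matrix(cfg$base_tensor, M, M * p)     # lag-blocked
  Acoup <- matrix(cfg$coupled_tensor, M, M * p)

  coupled <- rep(FALSE, N)
  windows <- NULL
  for (s in cfg$spike_times) {
    a <- max(1L, as.integer(round((s - cfg$coupling_lead) * cfg$fs)) + 1L)
    b <- min(N, as.integer(round((s + cfg$coupling_tail) * cfg$fs)) + 1L)
    coupled[a:b] <- TRUE
    windows <- rbind(windows, c(from_s = s - cfg$coupling_lead,
                                to_s = s + cfg$coupling_tail))
  }

  E <- matrix(rnorm(M * N, sd = cfg$noise_sd), M, N)
  y <- simulate_tvmvar_cpp(Abase, Acoup, as.integer(coupled), E, p)
  rec <- eeg_recording(y, cfg$fs, cfg$channel_labels,
                       reference = "synthetic")
  truth <- structure(list(
    source_channel = cfg$source_channel,
    source_targets = cfg$source_targets,
    coupling_windows_s = windows,
    background_sources = cfg$background_sources,
    spike_times_s = cfg$spike_times,
    base_adjacency = (apply(abs(cfg$base_tensor), c(1, 2), max) > 0) * 1 -
      diag(M),
    coupled_adjacency = (apply(abs(cfg$coupled_tensor), c(1, 2), max) > 0) * 1 -
      diag(M),
    seed = cfg$seed), class = "sim_truth")
  list(recording = rec, truth = truth)
}

# inter-ictal discharge template: a short run of biphasic spike-and-slow-
# wave complexes (default three), as in a ~1 s paroxysm; each complex has
# zero net area (sub-hertz energy would otherwise ring the 0.5 Hz
# high-pass far beyond the discharge itself). Returns the waveform and
# the 0-based offset of the middle complex peak (the labeled peak).
.spike_template <- function(fs, amp, spike_ms, wave_ms, n_complexes = 5) {
  n1 <- max(3L, as.integer(round(fs * spike_ms / 1000)))
  n2 <- max(3L, as.integer(round(fs * wave_ms / 1000)))
  sharp <- amp * sin(pi * (seq_len(n1) - 0.5) / n1)^2
  wave <- -sin(pi * seq_len(n2) / (n2 + 1))
  wave <- wave * sum(sharp) / sum(-wave)
  complex_ <- c(sharp, wave)
  w <- rep(complex_, n_complexes)
  mid <- (n_complexes - 1L) %/% 2L
  peak <- mid * length(complex_) + as.integer(ceiling(n1 / 2)) - 1L
  list(w = w, peak = peak)
}

#' Add spike-and-wave transients to a recording
#'
#' At each spike time the template is added to the source channel at zero
#' delay and to every other channel after its propagation delay with the
#' configured attenuation, emulating the characteristic inter-ictal
#' discharge peak propagating out of the epileptogenic zone.
#'
#' @param rec An `eeg_recording` (typically from [simulate_tv_mvar()]).
#' @param cfg The `sim_config` that generated it.
#' @return The recording with transients added.
#' @export
inject_spikes <- function(rec, cfg) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(cfg, "sim_config"))
  if (length(cfg$spike_times) == 0L || cfg$spike_amp == 0) return(rec)
  tpl <- .spike_template(rec$fs, cfg$spike_amp, cfg$spike_ms, cfg$wave_ms)
  M <- nrow(rec$data); N <- ncol(rec$data)
  src <- if (!is.null(cfg$source_channel))
    match(cfg$source_channel, rec$channel_labels) else 1L
  # the source leads every other channel; a coupled target receives the
  # template after its own propagation lag, other channels after the
  # base delay
  lag_ms <- rep_len(cfg$coupling_lag, max(1L, length(cfg$source_targets))) /
    cfg$fs * 1000
  delay_smp <- vapply(seq_len(M), function(m) {
    if (m == src) return(0L)
    ti <- match(rec$channel_labels[m], cfg$source_targets)
    ms <- if (!is.na(ti)) lag_ms[ti] else cfg$prop_delay_ms + 0.25 * m
    as.integer(round(ms * rec$fs / 1000))
  }, 0L)
  for (s in cfg$spike_times) {
    pk <- as.integer(round(s * rec$fs))          # 0-based peak sample
    for (m in seq_len(M)) {
      start <- pk - tpl$peak + delay_smp[m]      # 0-based
      idx <- start + seq_along(tpl$w) - 1L
      if (min(idx) < 0L || max(idx) >= N)
        stop("spike at ", s, " s overlaps the recording edge")
      gain <- if (m == src) 1 else cfg$attenuation
      rec$data[m, idx + 1L] <- rec$data[m, idx + 1L] + gain * tpl$w
    }
  }
  rec
}

#' Write a self-contained synthetic dataset to disk
#'
#' Presets:
#' \describe{
#'   \item{`null_independent`}{16 independent channels (no coupling, no
#'     spikes); the events file lists marker times so the segments can be
#'     epoched. Used to calibrate the surrogate test's false-positive
#'     rate.}
#'   \item{`two_channel_driver`}{Two channels where channel 1 drives
#'     channel 2 around a single labeled discharge.}
#'   \item{`full16_planted_source`}{16 channels, five discharges 10 s
#'     apart, source F7 coupling to six neighbours from 0.5 s before each
#'     peak (62.5 ms propagation lag), and a background-active occipital
#'     channel (O1) carrying a high-amplitude rhythm with mild permanent
#'     outflow to its neighbours.}
#' }
#'
#' @param preset One of `"null_independent"`, `"two_channel_driver"`,
#'   `"full16_planted_source"`.
#' @param seed RNG seed.
#' @param dir Output directory (created if needed). Default `tempdir()`.
#' @return List with `edf`, `events`, `truth_json` paths, the `truth`
#'   object and the `config` used.
#' @export
make_fixture <- function(preset = c("null_independent", "two_channel_driver",
                                    "full16_planted_source"),
                         seed = 1, dir = tempdir()) {
  preset <- match.arg(preset)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- switch(preset,
    null_independent = sim_config(
      n_channels = 16, duration = 20, spike_times = numeric(0),
      base_tensor = array(0, dim = c(16, 16, 2)),   # independent white noise
      seed = seed),
    two_channel_driver = sim_config(
      n_channels = 2, channel_labels = c("drv", "rcv"), duration = 14,
      source_channel = "drv", source_targets = "rcv", coupling = 0.5,
      spike_times = 7, seed = seed),
    full16_planted_source = {
      ns <- rep(10, 16)
      ns[match("O1", standard_1020_labels())] <- 25   # background rhythm
      sim_config(
        n_channels = 16, duration = 52, ar_r = 0.85, noise_sd = ns,
        source_channel = "F7",
        source_targets = c("Fp1", "Fp2", "F3", "C3", "P3", "T3", "T5"),
        coupling = 1.0, coupling_lag = c(24, 28, 32, 36, 40, 44, 48),
        spike_amp = 200,
        coupling_tail = 2.5,
        spike_times = c(7.5, 17.5, 27.5, 37.5, 47.5),
        background_sources = list(O1 = c("O2", "P3", "P4", "T5")),
        background_coupling = 0.55,
        seed = seed)
    })

  sim <- simulate_tv_mvar(cfg)
  rec <- inject_spikes(sim$recording, cfg)
  edf <- file.path(dir, paste0(preset, ".edf"))
  write_edf(rec, edf)
  ev_times <- if (preset == "null_independent") c(6.5, 13.5) else cfg$spike_times
  events <- file.path(dir, paste0(preset, "_events.csv"))
  write_events(discharge_events(ev_times, label = preset), events)
  truth_json <- file.path(dir, paste0(preset, "_truth.json"))
  tr <- sim$truth
  jsonlite::write_json(list(
    preset = preset, seed = seed,
    source_channel = tr$source_channel,
    source_targets = tr$source_targets,
    background_sources = tr$background_sources,
    spike_times_s = tr$spike_times_s,
    coupling_windows_s = as.data.frame(tr$coupling_windows_s),
    event_times_s = ev_times), truth_json,
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  list(edf = edf, events = events, truth_json = truth_json,
       truth = sim$truth, config = cfg)
}
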