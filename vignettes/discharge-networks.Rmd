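---
title: "Time-varying directed EEG networks and epileptogenic-zone localization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-varying directed EEG networks and epileptogenic-zone localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adtfnet)
```

## The problem

Inter-ictal discharges — spikes and spike-and-wave complexes between
seizures — typically originate in the epileptogenic zone (EZ) and
propagate to other cortical regions. If the *direction* of information
flow around each discharge can be estimated from scalp EEG, the electrode
whose outflow rises earliest, apart from channels that are already busy
before the discharge, marks the EZ candidate. `adtfnet` implements this
analysis as a reusable pipeline: time-varying MVAR modeling with a Kalman
filter, adaptive directed transfer function (ADTF) connectivity,
surrogate-based edge significance, and out-degree-based localization,
together with a synthetic EEG generator so that every stage can be
validated without clinical recordings.

## Signal model and procedure

Each discharge-centred segment `X(t)` (channels x time) is modeled as a
time-varying MVAR process

    X(t) = sum_{i=1}^{p} A(i, t) X(t - i) + E(t)

with coefficient matrices `A(i, t)` tracked by a random-walk Kalman
filter and innovation process `E(t)`. In the frequency domain,

    A(f, t) = I - sum_k A_k(t) e^{-j 2 pi f dt k},   H(f, t) = A(f, t)^{-1}

and the normalized ADTF

    gamma2_ij(f, t) = |H_ij(f, t)|^2 / sum_m |H_im(f, t)|^2

measures the directed flow from channel `j` to channel `i` as a share of
everything flowing into `i` (each receiver row sums to one). `Q2_ij(t)`
averages `gamma2` over the band of interest (0.5–14.5 Hz by default) and
the total outflow of node `j` is the mean of `Q2_kj(t)` over receivers
`k != j`.

Edges are declared significant against a phase-randomization null:
surrogates preserve every channel's amplitude spectrum while destroying
cross-channel phase structure, each surrogate is passed through the
identical Kalman + ADTF chain, and the observed `Q2` is referred to the
Gaussian upper tail of the surrogate distribution at `alpha = 0.01`,
one-sided. The binary dynamic network is reduced to a time-varying
out-degree matrix `k_i(t)`, binarized at out-degree `> 3`, and the EZ
electrode is the earliest non-background channel with sustained strong
outflow; per-segment results are aggregated across a patient's
discharges by majority vote.

## The analysis protocol and its defaults

Settings with published protocol values are the defaults everywhere:
common-average reference; 0.5–30 Hz zero-phase band-pass; 6-s segments
(3 s either side of the labeled discharge peak); factor-8 decimation to
32 Hz (192 samples, peak at offset 96); AIC order search nominally over
2–20; ADTF band 0.5–14.5 Hz on a 0.5-Hz grid; 200 surrogates;
significance 0.01; out-degree threshold 3.

Four points deserve explanation because the protocol leaves them open and
the sample geometry makes them matter.

**Order-search feasibility.** With `M = 16` channels and `N = 192`
samples, ordinary least squares supports at most `p ≈ 11` lags, and near
that edge the residual covariance collapses and the AIC plunges towards
the singular boundary rather than the parsimonious optimum.
`select_order()` therefore restricts candidates to orders with at least
two observations per regressor (`N - p >= 2 M p`, so `p <= 5` at the
16-channel geometry, while 3-channel test systems retain the full 2–20
range). The common-average reference also makes the channel space
(M-1)-dimensional; the AIC's log-determinant is computed on the
informative subspace.

**Kalman operating point.** The tracker's state holds `M^2 p`
coefficients — 1280 at `p = 5` — while a segment has 192 samples. Two
pipeline choices make this workable. First, each segment carries 3 s of
pre-epoch context (`burn_in_s`): the filter converges on the
pre-discharge data and the context is trimmed from all connectivity
grids, so the analysis window is exactly the 6-s epoch. Second, the
filter starts from zero coefficients with a deliberately small state
covariance (`init_cov = 0.001` with `uc = 0.01`), keeping it below its
asymptotic gain. A conservative tracker has an important side effect on
inference: phase-randomized surrogates cannot inflate their
cross-coefficients either, so the null distribution of `Q2` stays tight
and true edges stand out. `tvmvar()` itself defaults to the neutral
identity state covariance, which is appropriate for long stationary
records (the convergence checks in the test suite use it).

**Null calibration.** The null distribution of an integrated-ADTF share
is strongly right-skewed, and summarizing it by a raw-scale mean and
variance mis-calibrates the Gaussian 1% tail roughly three-fold (we
measure an edge-wise false-positive rate of about 0.03 on independent
channels). The pipeline therefore takes the surrogate moments on the
`log(Q2 + 0.001)` scale, where the same two-moment Gaussian test is
calibrated almost exactly at `alpha` (measured false-positive rate
≈ 0.010 at `alpha = 0.01` with 50 surrogates). This is the identical
test family — only the scale on which the two moments summarize the
surrogate distribution changes.

**Localization robustness.** Two parameters harden the earliest-
appearance rule against single-sample noise. The pipeline's background
window spans the segment start up to 1 s before the peak — the
pre-discharge out-degree pattern is what "background" means — so that
channels with persistent baseline outflow are excluded from EZ candidacy
and the decoy-prone scan region shrinks. And a channel must sustain
strong outflow for at least 4 consecutive samples (125 ms at 32 Hz):
empirically, false runs from estimation noise last 2–5 samples while
genuine source activations usually last tens of samples, so this
separates them well (`locate_ez()` alone defaults to 2 samples, the most
permissive sensible guard). Patient-level vote ties are broken by the earliest
median onset, in the spirit of the earliest-appearance rule itself.

## What the synthetic generator emulates

`make_fixture("full16_planted_source")` builds a 16-channel, 256-Hz
recording with:

* a stable oscillatory AR(2) baseline per channel (pole radius 0.85 at
  6 Hz — a theta-range rhythm inside the analysis band);
* a planted source (F7) whose directed coupling to seven neighbours
  switches on 0.5 s before each discharge peak and stays on for 2.5 s
  after it, with propagation delays staggered across targets
  (94–188 ms);
* five discharges, 10 s apart, each a five-complex spike-and-wave train
  (~1.35 s, 200 µV peak) that appears on the source first and on each
  coupled neighbour after its propagation delay;
* one background-active occipital channel (O1) with a 2.5x-amplitude
  rhythm and moderate permanent outflow to four posterior neighbours.

Several generator choices respond to identifiability pitfalls that are
worth knowing about because they affect real data too:

* **Couplings are additive signal mixing.** The coupled channel receives
  `b * source(t - d)` in its *output*, realized by AR-compensated
  coefficients at lags `d, d+1, d+2`. Feeding the source into the
  target's innovation input instead would pass it through the target's
  resonant AR dynamics and blow its variance up nearly an order of
  magnitude, after which the common-average reference smears the blast
  into every channel and no method can attribute direction.
* **Propagation lags clear the decimation smear and are staggered.**
  The anti-alias filter spreads a copy over roughly ±1.5 samples at
  32 Hz, so a sub-sample or 1-sample lag leaks into instantaneous
  correlation, which carries no direction; the shortest lag used is
  ~94 ms (3 samples at 32 Hz). Delays also differ across targets:
  when every target carries the same copy of the source's past at the
  same lag, the fitted model can represent that shared history through a
  single target and substitute it for the source in the other
  equations — a winner-take-all collapse that breaks recovery in a
  sizeable fraction of realizations.
* **Discharge complexes have zero net area.** A biphasic template with a
  DC residue rings the 0.5-Hz high-pass for seconds — in both time
  directions, because the filtering is zero-phase — and the discharge
  leaks backwards into the baseline.
* **Discharges are spaced 10 s apart** so that no segment's burn-in
  context overlaps a neighbouring discharge's coupled epoch.
* **Background strength is a compromise.** Background outflow must be
  strong enough that its channel is reliably excluded (its out-degree
  pattern must clear the binarization threshold throughout the
  baseline), yet a very strong broadcast rhythm lets arbitrary channels
  act as proxies for it through the common-average reference, which
  elects false senders.

What passing these tests does *not* show about clinical EEG: the
generator has no volume conduction beyond the reference, no artifacts
(ocular, muscle, electrode), Gaussian innovations, a single stationary
background topology, and discharge morphology far more stereotyped than
real inter-ictal activity. The validation demonstrates that the pipeline
is correct and well-calibrated under its own assumptions, not that those
assumptions hold on any particular recording.

## Numerical choices

* Band-pass filtering is a cascaded Butterworth high-pass + low-pass
  (order 4 each), zero-phase via forward–backward application; a single
  band-pass prototype with a 0.5 Hz edge at 256 Hz is numerically
  fragile in transfer-function form.
* Decimation applies a zero-phase order-6 Butterworth low-pass at 80% of
  the target Nyquist before keeping every 8th sample.
* Band integration divides by the number of frequency bins in the band,
  which keeps `Q2` inside [0, 1] on any grid; the literal `f2 - f1`
  divisor agrees only on a 1-Hz grid (regression-tested).
* Per-(f, t) inversion of `A(f, t)` is flagged unavailable beyond a
  condition number of 1e12; unavailable points carry `NA`, never zeros.
* The innovation covariance is an exponentially weighted average, which
  is symmetric positive semi-definite by construction.
* Surrogate fits that diverge are dropped; a run fails if more than 10%
  drop. With a fixed seed the whole surrogate pipeline is
  bit-reproducible.
* Sample windows are half-open, 0-based; the labeled peak maps to sample
  `round(peak_time * fs)`.

## Problem sizes used in the validation suite

The packaged tests and the acceptance script run entirely on synthetic
data at desk scale: 100 random 3-channel models for the normalization
property; 20 seeded independent-channel recordings (one segment each, 50
surrogates) for the false-positive calibration; 2000-sample records for
the Kalman convergence checks; and 20 seeded five-discharge recordings
(50 surrogates per segment) for end-to-end source recovery. The
surrogate count is reduced from the protocol's 200 to 50 in these
validation runs; the pipeline default remains 200.

## Limitations

Scalp-level localization names an electrode, not a cortical source; the
method inherits every limitation of scalp EEG (reference dependence,
volume conduction, low spatial resolution). The out-degree threshold of
3 is tied to a 16-channel montage; denser montages would need a
rescaled threshold. Manual discharge labeling is assumed — automatic
spike detection is out of scope — and the MVAR order cap imposed by the
192-sample segments limits spectral resolution at the low end of the
band.
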