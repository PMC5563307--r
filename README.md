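# adtfnet

Time-varying directed EEG networks and epileptogenic-zone localization
from inter-ictal discharges.

Inter-ictal discharges (spikes and spike-and-wave complexes between
seizures) usually originate in the epileptogenic zone and propagate to
other cortical regions. `adtfnet` estimates the *direction* of
information flow around each labeled discharge from multichannel scalp
EEG and names the electrode whose outflow rises earliest — apart from
channels that are already busy before the discharge — as the
epileptogenic-zone candidate. It is aimed at EEG methods researchers who
want a tested, reproducible implementation of the full analysis chain,
with a synthetic generator so every stage can be validated without
clinical recordings.

## Method

Each 6-s discharge-centred segment `X(t)` is modeled as a time-varying
MVAR process, `X(t) = sum_i A(i,t) X(t-i) + E(t)`, with the coefficient
matrices tracked by a random-walk Kalman filter and the model order
chosen by `AIC(p) = ln det(chi) + 2 M^2 p / N`. In the frequency domain,
`H(f,t) = (I - sum_k A_k(t) e^{-j2pi f dt k})^{-1}` and the normalized
adaptive directed transfer function

    gamma2_ij(f,t) = |H_ij(f,t)|^2 / sum_m |H_im(f,t)|^2

quantifies the directed flow j → i. `gamma2` is averaged over the
0.5–14.5 Hz band (`Q2_ij(t)`), edges are tested one-sided at
significance 0.01 against a phase-randomization surrogate null, the
binary network is reduced to a per-channel out-degree `k_i(t)`,
binarized at `k > 3`, and the earliest non-background channel with
sustained strong outflow is reported; discharges are aggregated per
patient by majority vote. The methods vignette
(`vignettes/discharge-networks.Rmd`) documents the model, the numerical
choices, and what the synthetic validation does and does not show.

## Worked example

Generate a synthetic 16-channel recording with a planted source (F7)
driving seven neighbours from 0.5 s before each of five discharges, plus a
background-active occipital channel, then run the full pipeline:

```r
library(adtfnet)

fx <- make_fixture("full16_planted_source", seed = 7, dir = tempdir())
res <- run_pipeline(list(edf = fx$edf, events = fx$events,
                         n_surrogates = 50, seed = 7))
res
#> <ez_pipeline_result> 5 segment(s), MVAR order 5 (selected: 5, 5, 5, 5, 5)
#> <ez_localization> electrode F7 (5/5 votes of 5 segments)
#>   background channels: O1
```

The report names electrode F7 — the planted source — with all five
discharge segments voting for it, and lists O1, the channel with
permanent baseline outflow, as excluded background. With an `outdir` in the configuration the run also writes
per-segment connectivity (`q2_seg*.csv`), binary-network edge lists,
out-degree matrices, a `localization.json` report and a reproducibility
manifest. A thin command-line driver with `simulate` / `analyze` /
`locate` subcommands is installed under `inst/cli/adtfnet.R`.

Lower-level entry points mirror the analysis stages: `read_edf()` /
`read_events()` / `preprocess_segments()` for ingest, `select_order()`
and `tvmvar()` for model fitting (a classed fit with `coef`, `summary`,
`predict`, `plot`, `simulate` methods), `adtf()` for connectivity,
`build_null()` / `threshold_network()` for surrogate thresholding, and
`out_degree_matrix()` / `locate_ez()` / `aggregate_patient()` for
localization.

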