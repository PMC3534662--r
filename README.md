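# tempotron: spike-latency readout of retinal population codes

Certain retinal ganglion cells — the salamander "fast-Off" type — encode a
newly fixated image in the *timing* of their first spike after image onset:
the burst latency is cosine-tuned to how much of the receptive field turned
dark. This package implements, and lets you dissect, the simplest downstream
circuit that can exploit that code: a single current-based integrate-and-fire
neuron (the **tempotron**) that classifies an input spike volley by firing at
least one spike (target) or staying silent (null).

The subthreshold voltage is a weighted sum of unit-peak postsynaptic
potentials over all afferent spikes t_ij,

    V(t) = sum_i w_i sum_j R_ij K(t - t_ij),
    K(t) = V0 (exp(-t/tau_m) - exp(-t/tau_s)),   tau_m > tau_s > 0,

with optional short-term synaptic depression R_ij (Tsodyks-type resource
depletion with utilization U and recovery time constant tau_D; R_ij = 1 for
static synapses). After an error trial, each efficacy moves by

    dw_i = +/- lambda sum_{t_ij < t_max} R_ij K(t_max - t_ij)

(t_max = time of the voltage maximum; positive after a miss, negative after a
false alarm), accelerated by a momentum term. The package computes V's global
maximum *exactly* by event-driven closed-form maximization within each
inter-spike interval (no time discretization), in compiled code.

Around that core the package provides:

* **spike I/O** — plain-CSV spike and stimulus tables, spike-count/latency
  restriction (`read_spike_table()`, `restrict_spikes()`);
* **benchmark decoders** — spike-count perceptron, temporal winner-take-all
  (first spike or 3-spike majority), rank-order decoder
  (`perceptron_fit()`, `twta_fit()`, `rank_fit()`);
* **task protocols** — the 8 luminance / 4 boundary realizations of the
  8-grating classification tasks, best-over-runs training, 75/25
  cross-validation with training margins, contrast generalization, and
  population resampling (`enumerate_realizations()`, `run_protocol()`,
  `crossvalidate()`, `contrast_generalization()`);
* **tuning analysis** — cosine tuning fits for first-spike latency and spike
  count with single-trial and per-phase-mean coefficients of determination,
  pairwise latency correlations and the trial-shift control (`fit_cosine()`,
  `latency_correlation()`, `shift_trials()`);
* **two-afferent analytics** — the exact map from relative latency to peak
  voltage, decision-boundary solving and its inverse (which weights realize
  requested boundaries), threshold-noise error integrals, and readout-time
  sweeps (`vmax_of_dt()`, `weights_for_boundaries()`, `optimize_pair()`);
* **a synthetic fast-Off population generator** — cosine-tuned latencies and
  counts in ~180 deg antiphase, uniform phase offsets, additive shared
  contrast shifts, shared + private latency jitter, bursts, low-contrast
  failures (`sample_population()`, `simulate_dataset()`) — plus the
  7-cell hexagonal schematic (`hex_schematic()`) and the
  phase-invariant orientation-tuning experiment on 200 model cells
  (`build_grid()`, `train_orientation()`, `tuning_curves()`).

The recordings behind the original analyses are not public, so the synthetic
generator stands in for them; every pipeline stage runs end-to-end on it.

## Worked example

Simulate an 8-cell fast-Off population, keep only first spikes, and train the
tempotron on a boundary task (detect a light/dark edge regardless of
polarity — gratings {1, 5} vs {3, 7}):

```r
library(tempotron)

pop <- sample_population(population_config(n_cells = 8), seed = 1)
ds  <- simulate_dataset(pop, trials_per_condition = 15, contrasts = 47, seed = 2)
ds1 <- restrict_spikes(ds, k_max = 1)          # first spike per cell

spec <- enumerate_realizations("boundary")[[1]]  # {1,5} vs {3,7}
fit  <- run_protocol(ds1, spec, "tempotron", lambda_grid = c(1e-3, 1e-2),
                     init_sd_grid = 0.05, runs = 2, cycles = 500)
fit$best_correct
#> [1] 1
round(fit$best_model$weights, 3)
#> [1]  0.111  0.019 -0.009  0.055  0.378  0.098  0.025  0.874

perc <- run_protocol(ds, spec, "perceptron", lambda_grid = c(1e-3, 1e-2),
                     init_sd_grid = 0.05, runs = 2, cycles = 500)
perc$best_correct
#> [1] 0.6536667
```

The tempotron solves the boundary task perfectly from single spike times
(fraction correct 1), while the spike-count perceptron — same free
parameters, but blind to timing — stays near 65%: separating "cells fire
together" from "cells fire apart" is an XOR-like problem that no weighted
count sum can cut. The fitted tuning curves behind these responses:

```r
ft <- fit_population_tuning(ds, contrast = 47)
head(ft[ft$measure == "latency", ], 3)
#>   cell measure baseline amplitude phase_offset r2_single r2_mean
#> 1    1 latency     86.0      21.6        234.6     0.969   0.999
#> 3    2 latency     77.0      25.7         92.3     0.977   0.999
#> 5    3 latency     95.6      20.9        172.6     0.969   0.999
```

Baselines near 80 ms, modulations near 25 ms, single-trial R^2 near 0.97 —
the latency code the readout feeds on.

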