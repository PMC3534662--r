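---
title: "Reading a retinal spike-latency code with a tempotron: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reading a retinal spike-latency code with a tempotron: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tempotron)
```

This vignette is the package's account of its science: the readout model and
its assumptions, the parameters that matter, what the synthetic spike
generator does and does not emulate, and the numerical and design choices
made where the design was genuinely open.

## The readout model

Fast-Off retinal ganglion cells respond to the sudden appearance of a grating
with a burst whose *first-spike latency* is cosine-tuned to the grating's
spatial phase, while the burst's *spike count* is tuned in antiphase. The
package asks how much visual computation a single downstream neuron can
extract from that temporal code.

The readout is a current-based leaky integrate-and-fire neuron. Each input
spike at time $t_{ij}$ (afferent $i$, spike $j$) contributes a stereotyped
postsynaptic potential

$$K(t) = V_0\left(e^{-t/\tau_m} - e^{-t/\tau_s}\right), \qquad t > 0,$$

normalized so that $\max_t K(t) = 1$; the membrane voltage is
$V(t) = \sum_i \omega_i \sum_j R_{ij} K(t - t_{ij})$. The neuron *fires* when
$V$ reaches the threshold $\theta$ (fixed at 1; only the ratio of weights to
threshold matters, and `classify()` is exactly invariant under common
rescaling). Firing-vs-silence is the binary classification; no reset or
post-spike dynamics are modeled because every analysis here uses only the
peak voltage and the first threshold crossing.

Learning is error-driven: after a missed target, every efficacy grows by
$\lambda \sum_{t_{ij} < t_{\max}} R_{ij} K(t_{\max} - t_{ij})$, where
$t_{\max}$ is the time of the voltage maximum; after a false alarm the same
quantity is subtracted. A momentum term ($\mu \in [0,1)$) accumulates
updates. A pattern with no spikes (or one whose voltage never becomes
positive) has no defined $t_{\max}$ and receives no update — that state is
absorbing for the rule, which is one reason the training protocol always
takes the best of several independently initialized runs.

With short-term synaptic depression enabled, each spike consumes a fraction
$U$ of its synapse's resources, which recover with time constant $\tau_D$:
$R_1 = 1$ and $R_{j+1} = 1 - (1 - (1-U)R_j)\,e^{-\Delta t_j/\tau_D}$. The
limits pin the model down: $U = 1$ with $\tau_D$ much longer than the burst's
inter-spike interval discounts everything after the first spike
($R_2 < 0.02$ for a 5 ms interval at $\tau_D = 500$ ms), and $\tau_D \to 0$
recovers static synapses. The learning rule scales each spike's contribution
by its $R_{ij}$, so it reduces exactly to the static rule when depression is
off.

## Parameters and defaults

| parameter | default | units | why |
|---|---|---|---|
| `tau_m` | 10 | ms | postsynaptic integration in the few-to-tens-of-ms range is where the two-afferent noise analysis puts the error minimum; configurable everywhere |
| `tau_s` | `tau_m/4` | ms | fixed PSP shape; the conventional tempotron ratio |
| `threshold` | 1 | — | weights are expressed in threshold units |
| `step_size` λ | task grids `1e-4`–`1e-1` | threshold units/spike | maximal update per input spike; protocol searches a log grid |
| `momentum` μ | 0.9 (gratings), 0.99 (orientation) | — | the orientation value is the stated one; the grating value is a standard choice |
| `cycles` | 2000 (gratings), 10000 (orientation) | — | protocol lengths |
| `smooth_window` | 50 | cycles | centered moving average of the error curve; the model snapshot at its minimum is returned (earliest cycle on ties) |
| depression `U`, `tau_d` | 1, 500 ms | — | the "maximal depression" regime that isolates first spikes |

## The synthetic population

The recordings the analyses were designed around are not public, so
`sample_population()` / `simulate_dataset()` generate a stand-in fast-Off
population with the statistical structure the analyses actually rely on:

* per-cell cosine latency tuning $b + a\cos(\phi - \phi_0)$ with
  $b \sim N(80, 10)$ ms, $a \sim N(25, 5)$ ms (truncated to $b > a > 0$), and
  $\phi_0$ uniform on the circle;
* spike-count tuning in 180° antiphase, parameters drawn independently of
  the latency parameters (count baseline $N(3.5, 0.7)$, amplitude
  $N(1.5, 0.4)$ spikes, chosen so preferred-phase mean counts sit in the
  3.5–5.5 range across contrasts);
* additive latency shifts per contrast level (defaults $+30, +18, +8, 0$ ms
  at 23, 31, 39, 47 % Michelson) that are *common to all cells* — this is
  the structure that makes the tempotron's contrast invariance a pure
  time-translation argument;
* trial-to-trial latency jitter split into a shared component (drawn once
  per trial, added to every cell) and a private component (2 ms each by
  default, giving pairwise latency correlations of
  $\sigma^2_{sh}/(\sigma^2_{sh}+\sigma^2_{pr}) = 0.5$);
* bursts as a first spike followed by spikes at a fixed 8 ms interval within
  the 150 ms window, and spike failures whose probability rises from 0 at
  the highest contrast to 0.15 at the lowest.

What it does **not** emulate: receptive-field geometry for the 8-grating
experiments (phase offsets are drawn, not derived from positions),
non-Gaussian latency noise, intra-burst irregularity, adaptation across
trials, and any correlation between latency and count tuning parameters.
Passing tests on this generator therefore validate the *pipeline and its
qualitative structure* (which decoder can solve which task, and why), not
error rates on the original recordings.

For the orientation experiment the generator is geometric:
200 cells with Gaussian receptive fields (σ = 0.12 grating periods) placed
uniformly in a circle of radius 1.5 periods; a cell's latency is
$b + a\cos(\pi D)$ where $D$ is the fraction of its receptive field covered
by dark bars — monotone from bright-slow ($b+a$) to dark-fast ($b-a$), the
simplest cosine-in-coverage law consistent with fast-Off behavior. $D$ is
computed exactly as a 1-D Gaussian measure of the dark half-periods after
projecting the field onto the grating's modulation axis (tails summed until
below 1e-12). The orientation is canonicalized mod 180° so that
$\psi \to \psi + 180°$ is an exact invariance.

## Numerical choices

* **Peak voltage is computed exactly, not on a time grid.** Between spikes,
  $V$ is $A e^{-t/\tau_m} - B e^{-t/\tau_s}$, whose interior critical point
  has a closed form; the event-driven core (C++) scans intervals, keeps the
  running sums re-based to the current spike time so no exponential
  overflows, and compares interior and endpoint candidates. Tests verify
  agreement with an independent dense-grid maximization to better than
  1e-6 on random patterns (the grid oracle must include the spike times
  themselves: the global maximum can sit on a kink when an inhibitory PSP
  begins exactly at the excitatory peak).
* **First crossing times** are found by splitting each interval at its
  critical point into monotone pieces and bisecting (80 iterations).
* **Two-afferent boundary solving** (`weights_for_boundaries()`) uses damped
  Newton iteration with numerical Jacobians from a coarse grid scan, then
  validates that both requested boundaries are transversal threshold
  crossings; the degenerate family $\max(w) = \theta$ (voltage identically
  at threshold) satisfies the equations and must be rejected explicitly.
  Requests no kernel can serve (e.g. a silent interval extending far beyond
  the PSP support on one side only) fail with a message suggesting a
  different $\tau_m$.
* **Threshold-noise errors** integrate the Gaussian tail probability of a
  wrong decision over each stimulus's relative-latency Gaussian with a
  trapezoid rule on ±5 s.d. (201 nodes; 41–61 in grid searches).
* **Error-curve smoothing** uses partial windows at the edges, so early
  cycles are not discarded; ties go to the earliest cycle.
* **Degenerate inputs:** empty spike trains are legal everywhere — the
  tempotron treats them as zero voltage (a silent trial is a null decision),
  the winner-take-all votes null, the rank decoder contributes nothing for
  silent afferents (ranks count only firing afferents, in firing order).
  In the two-afferent analyses, trials where a cell is silent are classified
  from the remaining spikes rather than discarded or auto-failed; this is
  what makes performance at very small readout windows equal the chance
  level on balanced classes.

## Design choices where the design was open

* **Depression recursion.** The resource-depletion form above (with the
  released fraction absorbed into the normalization so $R_1 = 1$) was chosen
  because it reproduces the stated limits exactly; it is the standard
  depression-only reduction of the Tsodyks synapse model.
* **Task counting convention.** Luminance realizations are the 8 cyclic
  adjacent pairs $\{i, i+1\}$ vs $\{i+4, i+5\}$ (role swaps counted once per
  starting phase); boundary realizations are $\{i, i+4\}$ vs $\{i+2, i+6\}$
  for $i \in \{1,2\}$ with both role assignments — the unique convention
  giving exactly 8 and 4.
* **Margins.** A training margin $m$ makes a target count as an error unless
  $V_{\max} \ge \theta(1+m)$ and a null unless $V_{\max} \le \theta(1-m)$ —
  a symmetric multiplicative band. Test performance is always measured
  margin-free.
* **Orientation schedule.** The step size decays as
  $\lambda_n = \lambda_0/(1 + n/n_{1/2})$ with $n$ counting pattern
  presentations ($n_{1/2} = 2\times10^5$) and momentum 0.99.
  $\lambda_0 = 5\times10^{-4}$ was fixed by pilot runs on the reduced grid:
  larger values let the momentum-driven updates settle into non-decaying
  limit cycles on a handful of border stimuli. With these defaults roughly
  two-thirds to three-quarters of independent population/initialization
  draws reach zero error on the grid within 2000 reduced-grid cycles, so
  convergence counts are reported over several seeded runs and only a
  majority is expected.
* **Hexagonal schematic.** Weights are $+1$ on the three preferred-dark
  cells and $-1$ on the four flanks, with a dark/bright latency difference
  of 40 ms at $\tau_m = 10$ ms. The preferred grating then peaks at exactly
  3 (inhibition arrives after the excitatory peak), its polarity inverse at
  $\max_t[3K(t-\Delta) - 4K(t)] \approx 2.9$, and the best of the remaining
  126 patterns at 2 — so a high threshold detects one pattern
  (simple-cell-like) and a lower one both polarities (complex-cell-like).
  Shorter latency differences comparable to the PSP time-to-peak break the
  ordering: near-preferred patterns overtake the inverse.
* **Problem sizes.** The test suite and the acceptance script run at desk
  scale: 8-cell populations with 15 trials per condition for the decoder
  hierarchy, 25 trials per condition for contrast generalization, a
  41 × 21 phase-orientation grid (861 stimuli) with up to 2000 cycles for
  the orientation experiment, and 5–10 seeded runs per convergence count.
  The full-scale 201 × 101 grid with 10000 cycles is supported by the same
  code path (`build_grid(201, 101, ...)`) and is an overnight job.

## Known limitations

* The learning rule's absorbing silent state (all-inhibitory drive on every
  target) is handled by multiple runs, not by modifying the rule.
* `twta_fit()` enumerates all $2^N$ labelings and is capped at 25 afferents.
* The exhaustive pair searches use finite weight grids; reported optima are
  grid optima (tests compare like with like or against analytic limits).
* The rank-order decoder assigns ranks only among afferents that fired;
  whether silent afferents should consume ranks is undefined in its
  original description, and this choice is the one that keeps the potential
  invariant under common latency shifts.
* Orientation-grid training on the full grid is compute-bound (hours, not
  minutes); the reduced grid preserves the geometry (same angular coverage,
  coarser sampling) and is what the routine checks use.
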