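---
title: "Heterogeneous spike-phase quantization of chemosensor data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heterogeneous spike-phase quantization of chemosensor data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Electronic-nose sensor arrays deliver raw responses that are statistically
ill-behaved: analyte concentrations vary over orders of magnitude, sensor
transduction saturates, and the identity signal lives in the *pattern* of
partially selective responses rather than in their magnitudes. Spiking
networks that learn odor representations online — here, a model of the
olfactory bulb's external plexiform layer (EPL) with spike-timing-dependent
plasticity — require inputs whose activity distributions are regular: if one
analyte recruits 10% of the principal cells and another 90%, no single
excitation/inhibition balance serves both.

`hetquant` implements and evaluates a biomimetic signal-conditioning
cascade that addresses this:

1. **Divisive normalization** (glomerular layer): external tufted (ET) cells
   laterally shunt one another so that `ET(x) = x / ||x||_1`. This removes
   concentration as a factor but does *not* regularize the shape of the
   activation distribution across sensors.
2. **Spike-phase quantization**: each sensor column holds `duplication`
   mitral cells (MCs), leaky integrate-and-fire units riding a 50-ms
   inhibitory gamma cycle. An MC's activation is coded by its spike phase
   within the cycle (1–50; 0 = silent). The ET→MC synaptic weight determines
   the minimal ("detection-threshold") input that makes the cell fire at
   all.
3. **Gain diversification** (the core mechanism): instead of one shared
   weight, the weights within a column are `1/x`-distributed so that the
   cells tile equidistant detection thresholds across the normalized input
   range [0.01, 1]. The number of active MCs per column then approximates
   the column's input level, and — because the normalized input sums to
   one — the *total* number of active MCs per sample is nearly constant
   regardless of the analyte. That is the regularization effect this
   package exists to demonstrate.
4. **A granule-cell (GC) feature layer**: four GCs per MC, randomly
   connected with probability `1/duplication`, reachable only by
   near-coincident delayed MC spikes, and trained two-shot by an
   asymmetric Hebbian STDP rule.

## Model and parameters

All spiking units obey `tau_m dv/dt = I/g_L - (v - E)` integrated by
classical RK4 at 1-ms steps, with the input current held constant within a
step (the equation is linear, so RK4 at this resolution is accurate to
~1e-6 mV; the test suite verifies fourth-order convergence against the
closed-form solution). Parameters (units: ms, mV):

| parameter | MC | GC |
|---|---|---|
| `tau_m` | 4 | 4 |
| `g_L` | 1 | 1 |
| `E` (rest/reset) | −60 | −60 |
| `v_th` | −55 | −50 |

MCs additionally receive a sinusoidal drive spanning [−40, 0] with a 50-step
period; all voltages and refractory flags reset at every cycle boundary, so
each unit fires at most once per cycle and its spike step *is* the phase
code.

**Phase origin of the sinusoid.** The literature fixes the sinusoid's range
and period but not where in the cycle the permissive peak sits. We place it
at step 20 (`oscillator_config(peak_step = 20)`), for a structural reason:
the weakest detectable input spikes at the permissive peak plus the membrane
lag (≈4 steps), so with the peak at 20 *every* MC spike lands by ≈ phase 24.
The half-cycle (25 ms) MC→GC delay then guarantees that GC spikes (phase
≥ 27) occur strictly after all same-cycle MC spikes — "GCs fire only while
MCs are quiescent" — and that no synaptic event straddles a cycle boundary.
Centering the peak at mid-cycle instead lets near-threshold MCs spike at
phase ≈ 29, whose delayed pulses would wrap into the next cycle and allow
GCs to fire before MCs; we treat that as an inconsistent parameterization
and avoid it.

**Calibration constant.** The map from an intended detection threshold `x`
to a weight is `w = c / x`, where `c` is the smallest constant current that
makes an MC spike within one cycle given the LIF and oscillator parameters.
`c` depends on the transient interplay of leak and sinusoid, so
`calibrate_drive_constant()` finds it by bisection (tolerance 1e-4) on
simulated single-cycle runs rather than analytically; with the default
parameters `c ≈ 7.05`. A 10-point equidistant threshold grid on [0.01, 1]
then yields the 10 homogeneous gain levels (weights ≈ 7 to 705, with the
second-lowest gain ≈ 59 — a `1/x` weight distribution).

**STDP.** `Δw = a₊ · exp(−Δt/τ₊)` for causal pairs and
`−a₋ · exp(Δt/τ₋)` otherwise, with `a₊ = 0.3125`, `a₋ = 1.25`,
`τ₊ = τ₋ = 4` ms, applied once per cycle, clamped to [0, 30], initial
weight 25. Two readings of the published rule coexist: the amplitudes might
also be the exponential time constants. We adopt the standard form (τ = 4 in
the exponent) because an 0.3125-ms potentiation window would collapse the
rule to a near-delta function; `stdp_params(alpha_in_exponent = TRUE)`
switches to the literal reading. The *pre*-synaptic time entering the rule
is the synaptic arrival time (spike + 25 ms delay), not the somatic spike
time: with somatic times every causal pair would sit ≥ 25 ms apart and
potentiation (`exp(−25/4) ≈ 2e-3`) could never counteract depression,
leaving the learning rule inert. `epl_network(use_delay_in_stdp = FALSE)`
restores the somatic-time reading.

**GC synapses and coincidence detection.** An MC spike reaches its
connected GCs 25 ms later as an additive current transient of initial
magnitude `w` decaying with `tau_syn = 2` ms. The time constant is set by
two constraints, both verified in the test suite: a single spike, even at
the weight-clamp maximum of 30, peaks at 9.6 mV — below the GC's 10 mV
drive-to-threshold — so GC activation always requires input from multiple
MCs; and two typical (w = 25) spikes arriving within a few milliseconds do
fire the GC. The resulting coincidence window (~6 ms) matters because
heterogeneous quantization deliberately spreads MC spikes across phases: a
window of exactly one timestep would leave GCs responsive only to
identically-phased MCs, i.e. blind to the very representations the
quantization step constructs, whereas a few-millisecond window lets GCs
read phase-neighborhood structure.

**Rinse.** Between sample presentations the network sees one 50-step
all-zeros cycle. Pending delayed pulses are cleared at sample boundaries;
since GC spikes propagate nowhere (GC→MC inhibition is disabled throughout,
to isolate the quantization step) and STDP requires an MC spike within the
cycle, this clearing is unobservable in any logged quantity, and it makes
presentations exactly independent — a property the test suite checks
(`present(A); rinse; present(B)` equals `present(B)` fresh).

## Quantization conditions

* **homogeneous** — all `8 × duplication` weights equal to one of the 10
  gain levels; the control condition in which weight choice is a global
  hyperparameter.
* **uniform** — per column, `duplication` equidistant thresholds on
  [0.01, 1]: a flat prior on each sensor's response, fully data-blind.
* **scaled** — thresholds equidistant on [min, max] of each sensor's
  calibration observations (the fold's 16 training samples passed through
  the normalizer with learning off). If a sensor's observations collapse to
  a point `m`, the range guard falls back to `[m/2, m]`.
* **adaptive** — each sensor's observations are partitioned into
  `duplication` segments by exact Jenks natural breaks (Fisher's dynamic
  program, not the iterative heuristic — verified against exhaustive
  enumeration for n ≤ 12); thresholds are piecewise-linearly interpolated
  across the break points with an equal count per segment, so threshold
  density follows observation density. With a single segment this
  construction reduces exactly to the scaled condition. Calibrated
  thresholds are floored at the 0.01 detection limit so weights stay
  bounded.

The degenerate single-threshold grid (`n = 1`) maps to the top of the range,
the most conservative single detector.

## Synthetic data

The generators produce the two study datasets from an 8×8 sensor-by-analyte
affinity matrix with a balanced three-level binary hierarchy: affinity 1 on
the diagonal and 0.45/0.25/0.10 at tree distance 1/2/3 before tuning. The
matrix is then sharpened/flattened by `G_i ← G_i^α / ||G_i^α||_1` with α
chosen by bisection so the mean row-wise Hoyer sparsity
`(√N − l1/l2)/(√N − 1)` hits 0.4 (tolerance 1e-3) — moderately selective
sensors; the transform provably preserves within-row rank order. The
"overall" Hoyer measure is the arithmetic mean of the row scores.

* **concentration** dataset: a class-`k` sample is `c · G[, k]` with
  `c ~ Exponential(mean_k)`, `mean_k` log-spaced over one decade
  (1 … 10), plus zero-mean Gaussian per-sensor jitter with s.d. 3% of each
  sensor's noiseless dynamic range; negative readings are clipped at 0
  (sensors cannot report negative values). These defaults make the 8-class
  problem nontrivial but tractable for the downstream few-shot classifier.
* **saturation** dataset: the concentration samples pushed through a
  per-sensor sigmoid `1/(1 + exp(−s(r − t)))` with defaults `s = 10`,
  `t = 0.15`, chosen so the highest-concentration classes saturate most of
  their sensor readings (> 0.9) while low-concentration classes remain in
  the informative mid-range.

What the generators deliberately do **not** emulate: sensor drift,
temperature dependence, analyte mixtures, and correlated noise. Passing
tests therefore demonstrate the regularization/information properties of
the conditioning cascade under controlled affinity structure, not
performance on any physical sensor array.

## Evaluation harness

Each of the 104 design cells (10 gains × 4 duplications × 2 datasets
homogeneous; 3 heterogeneous conditions × 4 × 2) is evaluated by eight-fold
cross-validation over a 128-sample pool: per fold, 16 training samples (two
per class — two-shot learning) and 112 test samples (14 per class). Training
presents each sample for five gamma cycles with STDP on, rinsing between
samples; testing replays all test samples with learning off and logs the
fifth-cycle ET/MC/GC responses.

Two measures per layer:

* **Utilization regularization** — the sample (n−1) standard deviation,
  across test samples, of the percentage of units spiking in the logged
  cycle. Lower is better.
* **Information** — accuracy of an RBF-kernel SVM (via `e1071`/libsvm) on
  the layer's response vectors under a nested protocol: a stratified half
  of the 112 test responses drives a grid search (stratified four-fold,
  training on the *smaller* single-fold segment of 14 samples, consistent
  with few-shot deployment); the selected hyperparameters are then trained
  and tested on the other half under the same four-fold scheme, aggregating
  4 × 42 = 168 predictions, 21 per class. ET responses equal the normalized
  inputs and serve as the baseline.

The hyperparameter grids cover `C ∈ [1e-7, 1e9]` and `γ ∈ [1e-8, 1e10]` at
one point per two decades by default (ties resolved toward smaller `C`,
then smaller `γ`). RBF-SVM selection is insensitive to finer spacing on
these few-shot problems, and the two-decade grid keeps a full
multi-condition comparison tractable on a single CPU; both grids are
arguments of `svm_information()` and `run_condition()` for users who want
denser searches. Before fitting, feature columns that are constant across
all samples are dropped — they contribute zero to every pairwise squared
distance, so the RBF kernel and the fitted SVM are exactly unchanged.

Statistical reporting follows the fold structure: per cell and layer, the
mean accuracy over folds with its standard error and a t-based 95%
confidence interval (`report_runs()`). We do not reproduce the original
mixed-model inference; the package's test suite instead checks the paired
directional properties (uniform-heterogeneous ≥ best homogeneous gain in
accuracy, lower utilization spread, monotone accuracy gains with
duplication) directly.

## Problem sizes used by the test suite

The headline property check runs both datasets at duplications 4 and 16
with four folds, the uniform condition against all ten homogeneous gains —
44 runs, 176 fold-level simulations, each presenting 128 samples for five
cycles plus rinses. These sizes exercise every code path at the same
per-fold dimensions as the full design while keeping the suite comfortably
reproducible on one CPU; the full 104-run grid at eight folds is available
through `enumerate_design()` + `run_grid()`.

## Numerical and degenerate-input choices

* Threshold crossing is checked after each full RK4 step; the potential is
  reset to `E` on the step the crossing is detected.
* Simultaneous pre-arrival and post spike (Δt = 0) counts as causal
  (potentiation): the delayed arrival did drive the response.
* An all-zero input vector normalizes to all zeros (the rinse input) rather
  than raising a division error.
* `jenks_breaks()` reduces `k` with a warning when it exceeds the number of
  distinct values; interior class boundaries are reported as midpoints
  between adjacent class edges.
* The compiled (Rcpp) and pure-R simulation engines implement the identical
  update order and are tested for exact agreement; the R engine exists as a
  readable reference and for debugging.

## Known limitations

* The calibrated conditions floor thresholds at the 0.01 detection limit;
  sensors whose calibration observations sit entirely below it are
  represented by a compressed threshold ladder near the floor.
* GC→MC feedback (attractor denoising) is out of scope by design; GC
  responses here measure initial recruitment and STDP-shaped selectivity
  only.
* With 16 calibration observations and duplication 32, Jenks segments
  cannot exceed the number of distinct observations; the adaptive condition
  then interpolates across fewer segments than requested.
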