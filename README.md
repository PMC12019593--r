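# hetquant

Heterogeneous spike-phase quantization for chemosensor arrays: an
olfactory-bulb-inspired signal-conditioning network, its synthetic
electronic-nose benchmarks, and the evaluation harness that measures what
the conditioning buys you.

## The problem and who this is for

Gas-sensor ("electronic nose") arrays produce raw responses that are hard
for downstream spiking networks to learn from: analyte concentrations span
orders of magnitude, sensors saturate, and even after divisive
normalization different analytes recruit wildly different numbers of
neurons. This package is for computational-neuroscience and neuromorphic
researchers who want a desk-scale, fully reproducible implementation of the
biomimetic fix: duplicate each sensor's principal neurons and diversify
their gains.

The cascade, modeled on the olfactory bulb:

- **Glomerular layer**: external tufted (ET) cells apply divisive (shunting)
  normalization, `ET(x) = x / ||x||₁` — concentration invariance.
- **Quantization step**: each sensor column holds `d` (the *duplication
  factor*) mitral cells (MCs), leaky integrate-and-fire neurons
  (`τ_m dv/dt = I/g_L − (v − E)`, RK4 at 1 ms) riding a 50-ms gamma cycle;
  activation is coded by spike phase (1–50, 0 = silent), one spike per
  cycle. Synaptic weights `w = c/x` give each MC a detection threshold `x`;
  *heterogeneous* (1/x-distributed) weights tile thresholds across the
  input range [0.01, 1], so the number of active cells — and hence network
  load — is nearly constant across analytes. Variants calibrate the
  threshold range (*scaled*) or density (*adaptive*, via exact Jenks
  natural breaks) to held-out observations.
- **EPL layer**: granule cells (4 per MC, random connectivity with
  probability `1/d`) detect coincident delayed MC spikes and are trained
  two-shot with an asymmetric STDP rule (amplitudes 0.3125/1.25, τ = 4 ms,
  weights clamped to [0, 30]).

Evaluation measures **utilization regularization** (s.d. across test
samples of the % of units active per layer; lower is better) and
**information** (accuracy of nested, hyperparameter-optimized RBF SVMs on
each layer's responses, 168 aggregated predictions per run and layer)
under eight-fold, two-shot cross-validation over a 128-sample pool drawn
from two synthetic datasets (*concentration* and *saturation*) built on a
sparsity-tuned (Hoyer 0.4) hierarchical affinity matrix.

## Worked example

```r
library(hetquant)
library(dplyr)

G <- tune_sparsity(build_hierarchical_affinity())   # Hoyer measure 0.4
pool <- generate_concentration(G, generation_config(seed = 101))
pool
#> <hq_samples> concentration dataset: 128 samples x 8 sensors, 8 analyte classes
#> # A tibble: 128 x 9
#>   sensor_1 sensor_2 sensor_3 sensor_4 sensor_5 sensor_6 sensor_7 sensor_8 label
#> 1    0.464    0.241   0.0542   0.0656   0.0800   0.0221    0       0.0480     1
#> ...

folds <- make_folds(pool$label, seed = 8)           # 8 two-shot CV folds
two <- folds[1:2, ]; class(two) <- class(folds)     # quick demo: 2 folds
res <- run_condition(pool, two, "uniform", duplication = 8, seed = 1)
report_runs(res)
#>   condition duplication dataset       layer n_folds accuracy_mean util_mean util_std_mean
#> 1 uniform             8 concentration et          2         0.527      NA           NA
#> 2 uniform             8 concentration gc          2         0.307      25.8         6.11
#> 3 uniform             8 concentration mc          2         0.432      15.9         1.66
```

Reading this: the ET row is the normalized-input SVM baseline (accuracy
0.527 on this deliberately noisy 8-class problem). The MC layer retains
most of that information in its spike-phase code (0.432 at duplication 8)
while using a nearly constant ~16% of its cells per sample — the
utilization s.d. of 1.66 percentage points is the regularization the
1/x-distributed weights buy; a homogeneous-gain network on the same data
shows spreads several times larger. GC accuracy reflects two-shot STDP
recruitment of coincidence features, which sharpens with duplication. `autoplot()` methods exist
for sample sets (`autoplot(pool)`), schemes (`plot_scheme()`), and
summaries (`autoplot(report_runs(...), metric = "regularization")`).

The full experimental grid is enumerated by `enumerate_design()` (104
runs) and dispatched with `run_grid()`. A thin command-line front end
(`inst/cli/hetquant.R`) wraps `generate`, `run`, and `report`.

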