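# polefocus

Quantification of polar protein-cluster dynamics in rod-shaped bacteria
from time-lapse fluorescence microscopy — with a ground-truthed synthetic
microscopy generator so that every stage of the pipeline can be validated
by parameter recovery.

## The problem

Several bacterial proteins — among them Enzyme I (EI), the first
phosphotransfer protein of the PTS sugar-uptake system in *Escherichia
coli* — assemble into compact fluorescent foci at the cell poles, while a
second pool of the same protein stays diffuse in the cytoplasm. The
balance between the two pools, and the motion of the focus itself, varies
from cell to cell and over time: foci form stochastically from the
pre-existing diffuse pool, exchange molecules with it, gradually disperse
when quiescent cells resume growth, and are inherited asymmetrically at
division. Quantifying this behavior from two-channel movies (a
cell-body/phase channel plus a fluorescent-fusion channel) requires a
chain of image-analysis steps, each of which can silently bias the
biology-facing numbers. `polefocus` implements that chain and, crucially,
a generative model of the raw movies with complete ground truth, so the
chain is testable end to end.

## What the package measures

Per cell and frame, on the fluorophore channel restricted to the
segmented cell mask:

- **MI** — mean intensity, a proxy for protein amount;
- **SDI** — population standard deviation of intensity, the clustering
  proxy: a uniform cell has SDI 0, and moving a share *f* of the
  fluorophore budget into a focus raises SDI monotonically;
- focus detections (top-hat homogenization, then a mean + *k*·SD
  threshold within the mask), their areas and centroids;
- focus trajectories (nearest-neighbour linking) and the average speed
  `path length / elapsed time`;
- one of four localization patterns per cell: **non-Dyn** (static focus,
  maximum pairwise displacement < `d_static`), **Dyn-1P** (mobile within
  one pole zone), **Dyn-OP** (entering the opposite pole zone or the
  midcell band), **UC** (no detectable focus);
- formation events (SDI jump ≥ 2× the trailing-baseline median),
  gradual-dispersal events, quiescence-exit sub-populations
  (none / small / big focus by Otsu threshold on time-0 SDI),
  sister-cell inheritance fractions;
- FRAP recovery: pole-ROI series are drift-corrected by the whole-cell
  total and normalized to the bleached-away signal,
  `recovery(t) = (F̂(t) − F̂(0⁺)) / (F̂_pre − F̂(0⁺)) × 100`, with an
  optional `A(1 − e^{−kt})` exponential fit;
- Pearson/Spearman correlation (direct formulas, t-approximation
  p-values) and ordinary one-way ANOVA.

The synthetic generator renders rod-shaped cells (uniform diffuse fill +
Gaussian focus, exact per-cell budget conservation), grows and divides
them, moves foci by a confined random walk whose speed follows
`v = v0 (A_ref / A)^α`, nucleates foci with exponential waiting times,
disperses them linearly in time, bleaches pole regions with
exchange-driven recovery, and adds a reporter channel rank-correlated
with the clustering level through a Gaussian copula.

## Worked example

```r
library(polefocus)

cfg <- sim_config(n_cells = 50, n_frames = 11, seed = 42)  # 1-min frames
sim <- simulate_population(cfg)      # stack + ground truth
res <- run_analysis(sim$stack)       # segment, detect, track, classify
round(100 * res$fractions$fractions, 1)
#> non_dyn  dyn_1p  dyn_op      uc
#>      10      46      10      34

mm  <- match_tracks_to_truth(res$cells, sim$truth)
lab <- merge(res$labels, mm, by = "cell")
mean(lab$label == lab$pattern)       # classification accuracy vs truth
#> [1] 0.98
```

The fractions are the recovered shares of the four localization patterns
in this 50-cell movie (the generator drew 5/22/5/18 cells per class);
the last line says the pipeline recovered 49 of the 50 true class
labels.

FRAP, one condition:

```r
cfg <- sim_config(n_cells = 14,
                  frap = list(n_prebleach = 5, bleach_efficiency = 0.9,
                              exchange_rate = 0.005,
                              recovery_asymptote = 6.31,
                              duration = 600, interval = 10),
                  seed = 1)
frap <- simulate_frap_stack(cfg)
res  <- analyze_frap_stack(frap$stack, n_prebleach = 5)
recovery_fraction_at(res$mean_curve, 600)
#> [1] 5.878141
```

i.e. ~5.9% of the bleached pole signal has recovered after 600 s,
against an analytic ground-truth endpoint of 6%.

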