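---
title: "polefocus: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{polefocus: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`polefocus` pairs a measurement pipeline for polar protein-focus dynamics
in rod-shaped bacteria with a generative model of the raw movies. This
vignette is the package's account of both: the models and their
assumptions, the parameters that matter, the numerical choices, and what
passing the parameter-recovery suite does and does not establish about
real data.

## 1. The generative model

### Cell geometry and growth

Cells are horizontal spherocylinders (rods with hemispherical caps) of
width `cell_width` (default 1 µm) on a tile grid, one founder cell per
tile, so masks never overlap and cell identity is unambiguous. Initial
lengths are uniform on `cell_length_range` (default 2.5–4.5 µm); cells
elongate linearly at `growth_rate` (default 0.02 µm/min, a slow-growth
minimal-medium scale) and divide at `division_length` (default 5 µm)
into two equal daughters separated by a 0.3 µm septal gap. Daughters are
anchored at the septum and pushed outward as they grow, as on an agar
pad. The default pixel size is 0.1 µm; none of these scales is taken
from a specific instrument, they are typical *E. coli* imaging values.

### Fluorophore bookkeeping

Each founder draws a budget per unit length (`total_intensity_mean`,
`total_intensity_cv`), so the whole-cell amount grows with length and
the mean intensity (MI) stays constant through growth — protein
concentration homeostasis. A share `f` of the budget sits in at most one
compact focus rendered as a 2-D Gaussian of width `cluster_sigma`; the
Gaussian's pixel weights are renormalized over the cell mask, so the
per-cell budget is conserved **exactly** in every noise-free frame. This
makes the central biological claim testable by construction: focus
formation moves signal out of the diffuse pool without changing the
total, so MI is flat across a formation event while the SDI jumps.

The ground-truth focus area is the 1/e isophote of the Gaussian,
`A = 2πσ²` (the footprint containing 1 − 1/e of the spot signal). This
convention was chosen because it matches what a within-cell
mean + 2·SD threshold detects for the canonical spot size to within a
few percent; footprint conventions (FWHM, 1/e, 1/e²) differ only by a
fixed factor in σ and any one of them is defensible.

### The four localization patterns

The population mixture over {non-Dyn, Dyn-1P, Dyn-OP, UC} is realized
**exactly** by largest-remainder allocation with a seeded shuffle, not
by multinomial sampling: the generator emulates the observed composition
of a study population, and a benchmark whose input composition wobbles
binomially would conflate generator noise with pipeline error. Per-cell
and per-event randomness (motion, nucleation times, inheritance
outcomes, noise) remains stochastic. The same allocation is used for the
quiescence-exit class mixture; per-division inheritance stays a true
Bernoulli draw because the corresponding check is explicitly specified
against binomial spread.

Motion is a confined random walk. The expected per-step speed follows
the power law `v = v0 (A_ref/A)^α` (defaults `v0 = 0.03` µm/s,
`A_ref = 0.15` µm², `α = 1`), the simplest monotone law consistent with
an inverse speed–size trend; spot widths are drawn per pattern so that
static foci are the largest and pole-escaping foci the smallest. The
walk is substepped at ~10 s regardless of the frame interval, so long
intervals show diffusive, confined net displacement rather than one
straight jump — without this, a 60 s frame interval produces unphysical
per-frame displacements that no linking gate can follow. Reflection at
the zone bounds preserves step length, so the path-length speed
statistic is unbiased by confinement.

- **non-Dyn**: anchored at a pole with 5 nm jitter (zero drift).
- **Dyn-1P**: reflected walk within `[0.3 µm, 0.30·L]` of its pole —
  inside the pole zone with a small margin against the midcell band.
- **Dyn-OP**: reflected walk over the whole cell *plus* one relocation
  to the opposite pole at a time drawn uniformly within the canonical
  10-min observation window. The class is operationally defined by that
  relocation ("switches pole or moves to midcell"); a pure random walk
  leaves ~15% of Dyn-OP cells unexpressed within an 11-frame movie,
  which would be a generator artifact, not a classifier error. The
  relocation is suppressed in the speed benchmarks (copula and
  motility-suppressed modes), where speed itself is the measurand and a
  forced jump would contaminate it.
- **UC**: no focus; if `nucleation_rate` λ > 0 the cell nucleates after
  an exponential waiting time independent of length, then ramps its
  focus share linearly over `formation_duration` (default 3 min).
- Motility-suppressed (metabolic-inhibition) mode: speed is a
  size-independent residual `0.05·v0`, with lognormal cell-to-cell
  variability (CV ≈ 30%). The variability matters: with a strictly
  identical residual in every cell, the only between-cell variation in
  measured speed is the localization-noise floor, which grows slightly
  with spot size and would by itself induce a spurious positive
  speed–size correlation in an otherwise null condition.

Dispersal (quiescence exit) is linear: `f(t) = f₀(1 − r·(t − t₀))` with
`dispersal_rate` r = 0.02/min, i.e. a focus fully disperses in ~50 min —
gradual on the 15-min sampling grid. Re-forming cells re-enter the
nucleation pathway after dispersal completes; a re-formed focus does not
re-disperse within the movie.

At division the focus goes entirely to the daughter that contains it
with probability `inherit_single_prob`; otherwise it is split and both
daughters carry one. The budget share is rescaled by the mother/daughter
length ratio (capped at 0.8) so the focus keeps its absolute amount.

### Camera model

Background offset plus additive Gaussian read noise with SD equal to
`read_noise_frac` (default 2%) of the median per-cell diffuse signal.
Shot noise is deliberately omitted: additive noise keeps the variance
bookkeeping of the SDI proxy exact and deterministic. Consequences for
realism are discussed in §5.

### FRAP stacks

Static cells with one large non-dynamic polar focus. At the bleach, all
pixels within 0.35 of the normalized axis at the focus pole are scaled
by `1 − bleach_efficiency`. Recovery follows `A(1 − e^{−kt})` percent of
the bleached-away signal, applied per pixel in drift-corrected units,
with the unbleached cell region losing exactly what the pole gains
(exchange with the diffuse pool conserves the whole-cell total). Because
recovery is per-pixel linear, *any* sub-ROI of the bleached zone carries
the same normalized curve — the pipeline's pole ROI (axial ≤ 0.25) is a
strict subset of the bleached zone (≤ 0.35), so segmentation-boundary
pixels cannot bias the endpoint. The untreated condition's asymptote
includes the de-novo-synthesis contribution (about a third of the
recovered signal); the translation-inhibited condition is modeled by
configuring the correspondingly smaller asymptote with the same `k`
(same early kinetics). The double normalization implemented in
`normalize_recovery_curve()` — drift correction by the whole-cell total,
then bleach-depth normalization — is standard FRAP practice; the
generator defines its ground truth in the same units, which is the one
reading of "normalized to the total fluorescence" that makes generator
and pipeline self-consistent.

### The reporter channel and copulas

Reporter per-cell means are tied to the true clustering level through a
Gaussian copula: the clustering level is mapped to normal scores, an
independent normal is orthogonalized against them, and the two are mixed
so the **sample** latent correlation equals the configured value exactly
(for rank-correlation targets, the latent Pearson is set to
`2·sin(πρ_s/6)`). Exactness is a deliberate benchmark property: the
generated dataset carries the configured dependence, so any shortfall in
the recovered coefficient is attributable to the measurement chain, not
to copula sampling noise. The same construction drives the speed–size
benchmark, where each cell's speed scale is drawn against its spot
width.

## 2. The measurement pipeline

Segmentation is a global Otsu threshold on the cell-body channel, hole
filling, 8-connected labeling, an area window (0.5–20 µm²), and
discarding border-touching components (their geometry is truncated; this
keeps the length statistics unbiased). The commercial threshold tool the
workflow replaces is parameter-free here by design. Cell length is the
principal-axis extent of the mask plus one pixel; pole tips are the
extremal projected pixels; cells are linked across frames by maximum
mask overlap, and one-to-two overlap mappings declare a division.

Focus detection applies a white top-hat (disc radius 0.5 µm) for
**detection only**; areas, intensities and centroids are measured on the
original image. The threshold is within-cell mean + `k_sigma`·SD
(default 2) with a 0.04 µm² minimum area. Centroid weights are
background-corrected by the within-cell median so the diffuse pedestal
does not drag centroids toward the component's geometric center. Two
non-obvious facts shaped the defaults:

- the structuring element need not fit inside the cell width — when it
  does not, opening flattens the whole rod and the top-hat degrades
  gracefully to a background-subtracted cell — but a disc only slightly
  smaller than the width (9 px vs 10 px) generates interior ridge
  artifacts that read as false foci; 0.5 µm (11 px) is safe at the
  default geometry;
- for a noise-free Gaussian spot, the mean + k·SD threshold contour is
  amplitude-invariant: detected area responds to spot *width*, not to
  the budget share. SDI responds to the share. The two proxies are
  therefore complementary, and the SDI–area correlation check sweeps
  both together, as a real heterogeneous population does.

Trajectory linking is greedy nearest-neighbour with a 1 µm gate and no
gap bridging by default; speed is path length over elapsed time, the
right statistic for jagged paths. Pattern classification uses
`pole_zone_fraction = 0.25`, `d_static = 0.2` µm and
`presence_min = 0.2`; UC is decided first on presence, then non-Dyn on
maximum pairwise displacement, then Dyn-OP on any entry into the
opposite pole zone or midcell band relative to the starting pole (a
track starting outside both pole zones is Dyn-OP by convention). All
three thresholds are exposed as parameters.

Event detection: formation fires at the first frame whose SDI is at
least `jump_factor = 2` times the trailing 3-frame baseline median with
the focus present for two consecutive frames — the factor 2 reflects the
observed rough doubling of SDI upon formation. Dispersal requires a
monotone SDI run over 5 frames accumulating a 40% relative drop, or
focus absence for two frames. The quiescence small/big split uses Otsu's
threshold on the time-0 SDI distribution of focus-bearing cells,
overridable. Sister pairs are evaluated at their last common tracked
frame.

## 3. Benchmark recipes and their problem sizes

Each figure-analogue recipe (`run_figure_suite()`) simulates its inputs
at the study's stated conditions and recovers the quantity through the
full image pipeline:

| recipe | condition | size |
|---|---|---|
| fig1 | pattern mixture 9/43/11/37%, 11 frames at 1 min | 1000 cells, 10 fields |
| fig1e | speed–size copula at ρ_s = −0.78, 31 frames at 10 s | 120 cells |
| fig2 | nucleation λ = 0.015/min, 21 frames at 3 min | 100 cells |
| fig3 | FRAP endpoints 6% / 4% at 600 s, k = 0.005 s⁻¹ | 14 + 12 cells |
| fig5a | class mixture 13/64/23% at time 0 | 269 cells |
| fig5sisters | one division per mother, p_single = 0.72 | 200 divisions |
| fig5cd | reporter copula at ρ = −0.16 (and 0) | 500 (222) cells |

These sizes are the studies' own sample sizes; each recipe runs in
seconds to about a minute on one CPU, and the full acceptance script in
a few minutes. Batched recipes derive per-batch seeds from the single
run seed by a fixed affine map, so adding a batch never perturbs
another's draws.

Recipe-specific generator settings, chosen once at design time:

- **fig1e** fixes cell length (3.5 µm) and budget (CV 0): with a shared
  budget but varying length, the diffuse level — and hence the detection
  threshold — varies with length and confounds the area measurement
  (rank fidelity to true area drops from 0.998 to ~0.73). The benchmark
  isolates the focus properties. It also uses a 0.065 µm pixel — the
  scale of a 100× objective on a 6.5 µm-pixel sCMOS camera — to reduce
  area quantization across the spot-size range.
- **fig1** sets λ = 0 over the 10-min window: the four-way mixture
  already includes UC as a terminal label for that window.
- **fig2** scores only nucleations that are detectable in principle —
  onset at least `baseline_window` frames after track start and two
  frames before movie end; a windowed jump detector cannot place an
  event inside its own baseline.
- **fig5cd** draws the clustering level from a truncated normal
  (`cluster_fraction_dist = "normal"`) with narrow budget and length
  spread, so the observed SDI margin is approximately Gaussian and the
  measured Pearson is interpretable against the configured latent value.

## 4. Numerical and degenerate-input choices

SDI is the population (n-denominator) standard deviation — deterministic
and matching the plain reading of "standard deviation intensity".
Correlation p-values use the t-approximation (a permutation option
exists for small n); Spearman uses average ranks for ties. The ANOVA is
the textbook between/within mean-square ratio; two identical groups give
F = 0, zero within-variance with unequal means gives F = ∞ with p = 0.
Blank images segment to zero cells with a warning rather than an error;
a zero-variance series yields an `undefined` correlation flag; an
all-zero FRAP curve returns A = 0 with `k` unidentifiable and a
non-convergence flag; singleton trajectories carry `NA` speed and are
excluded from speed–size statistics. Linking ties break by smallest
distance then smallest observation index, making the pipeline fully
deterministic for a fixed stack; with a fixed seed, two simulate-analyze
round trips are byte-identical.

## 5. What the synthetic world does not model

No photophysics beyond the FRAP bleach itself (no blinking, no
acquisition bleaching), additive noise only (no Poisson shot noise, no
EM gain statistics), no 3-D point-spread function or defocus, no curved
or crowded cells (masks are ideal rods on a sparse grid), no
sub-resolution multi-focus structure, and motion is a reflected random
walk rather than a mechanistic polymer or membrane-interaction model.
Passing the recovery suite therefore establishes that the measurement
chain is unbiased *given* this image-formation model at realistic noise;
it does not establish robustness to segmentation-hostile real images
(dense colonies, uneven illumination, phase halos). The module
boundaries make those failure modes testable separately: each stage can
be fed real data or a harder generator without touching the others.

## 6. Known limitations

- The dyn-1P/dyn-OP boundary depends on `pole_zone_fraction`; the
  defaults separate the generator's canonical patterns, and real
  populations with intermediate behavior will show threshold
  sensitivity.
- The SDI–area proxy saturates for spot widths approaching the top-hat
  radius, where opening partially reconstructs the spot.
- Inheritance is evaluated at the last common frame of each sister
  pair; cells lost by segmentation before that frame drop out of the
  denominator.
- The FRAP generator's percent-recovery ground truth is defined in the
  pipeline's own normalized units; absolute-intensity readings of the
  same stacks would need their own reference.
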