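---
title: "Methods: spatial statistics and simulation of giant-cell patterning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial statistics and simulation of giant-cell patterning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`giantcell` quantifies the spatial arrangement of giant cells — highly
endoreduplicated, highly enlarged pavement cells — in segmented plant
epidermal tissue, and asks whether that arrangement is random, clustered,
or dispersed. It provides:

1. a data model for labeled rasters, per-cell shape features, and
   cell-adjacency graphs;
2. a shape- and size-preserving tissue randomization engine (the spatial
   null model) with a resampling-based one-sided test;
3. a synthetic tissue generator with planted spatial patterns, so the whole
   pipeline is testable without microscopy data;
4. a stochastic, cell-autonomous simulator of giant-cell fate commitment in
   a growing, dividing polygonal tissue;
5. cell-size-distribution comparison: 1-D Wasserstein distances with
   permutation tests, classical MDS embedding, and per-replicate
   normalization.

# The null model

Continuous point-process statistics (Ripley's K and relatives) are
inapplicable to confluent tissue: cells are extended regions whose contact
structure depends on their sizes and shapes, so a meaningful null must hold
those properties approximately fixed while shuffling positions. The engine
here rebuilds each image by (i) rotating every movable cell's pixel mask by
a uniform draw from a configurable range and re-anchoring it at a random
free location (placement in descending area order, rejection sampling with
an overlap cap), then (ii) assigning every remaining free pixel to the
nearest placed cell by multi-source breadth-first competition. Cells at the
image border are kept pixel-identical in every ensemble member
(cropped-image mode); for whole-tissue analyses the background is treated
as a single fixed cell instead and edge cells are shuffled too.

Per-cell areas are preserved tightly (Pearson r above 0.99 on the synthetic
tessellations used in the tests); shapes are preserved only approximately —
competition makes cells slightly more convex with noisier walls, the
artifact profile the reconstruction control is designed to expose. A
`reconstruct_tissue()` run anchors each cell at its own centroid plus at
most ±5 µm of uniform noise and keeps orientations, producing the same
artifact class without destroying the arrangement; comparing observed
statistics on reconstructions versus randomizations separates artifact
effects from genuine spatial signal. An optional 3×3 majority-label
smoothing pass (`smooth_iters`) is available as an error-correction step
but is off by default: the synthetic tessellations are already
smooth-walled, and smoothing cannot be allowed to grow fixed cells.

The internals of the original randomization tool are not published;
this engine is an explicit stand-in chosen to reproduce the documented
behaviour (sizes preserved, shapes approximate, border handling, ±π/6
orientation mode for anisotropic tissue). It is isolated behind
`randomize_tissue()` / `randomization_spec()` so an alternative engine can
be swapped in. Anchors are drawn uniformly over the free region by default;
an alternative `anchor_mode = "permute"` shuffles cells onto a permutation
of the original centroids. A paired probe over 150 generator seeds found no
significant mean bias for either mode.

# The test

The headline observable is the mean number of giant-cell neighbors per
giant cell on the cell-adjacency graph (edges require at least
`min_contact = 2` touching pixel pairs under 4-connectivity, suppressing
spurious corner contacts). Giant cells touching the image border are
excluded as counted centers but still count as neighbors of interior
giants. The one-sided p-value is the fraction of randomized images whose
statistic is the same as or more extreme than the observed one — ties count
as extreme, so with `n_random` images the smallest reportable value is
`1/n_random` and an observed value beyond every null value is reported as
`p < 1/n_random`. Replicates are pooled by index: the k-th null value pools
randomization k of every replicate, keeping exactly `n_random` null values.

Because ties are counted as extreme, the p-value is conservative on the
discrete grid of the statistic: under perfect exchangeability its
distribution sits slightly to the right of uniform. The calibration test
therefore compares the planted-random p-value distribution against the
exchangeable reference distribution (the p-value a randomization member
obtains against its peers) with a two-sample test, rather than against a
continuous uniform — that is what "uniform up to discreteness" means
operationally.

# The synthetic generator

`generate_tissue()` grows a space-filling tessellation from seed points:
each pixel joins the seed minimizing distance/radius, with radii drawn from
a log-normal body (`area_sdlog`, default 0.35) and a heavy tail
(`tail_fraction`, default 3%, area factor `tail_scale = 10`), dart-throwing
seed spacing, optional stomatal clusters (one small near-circular cell
ringed by 3–6 small cells) and optional anisotropy. Contiguity is enforced
by keeping each label's seed component and reassigning orphans. The
generator emulates the statistical structure the analysis relies on —
heterogeneous convex-ish cells, a minority of very large cells, small-cell
clusters, incomplete border cells — and deliberately not the lobed
puzzle-piece morphology of real pavement cells: the clustering statistics
operate on contact topology, which lobes affect only marginally. A green
test on synthetic tissue therefore establishes the statistical machinery,
not segmentation robustness on real images.

`plant_pattern()` selects cells (without altering geometry): uniformly at
random, clustered (sequential selection with probability boosted `1+boost`
fold for candidates adjacent to an already-selected giant; `boost = Inf`
forces a single clump), or dispersed (rejection of candidates adjacent to
selected giants). Eligibility mirrors the experimental controls: non-border
pavement cells above an area floor; the floor matters because the smallest
sliver cells have atypical contact statistics in any placement-based null.
With the default generator scale (~1 µm pixels, mean cell area ≈ 100–150
µm²) the sepal-analogue floor of 100 µm² is used throughout the tests.

# The giant-cell size threshold

The threshold is built from a reference genotype essentially lacking giant
cells: on the sorted pooled reference areas, the value at the 99.3rd
percentile (nearest-rank convention — the source does not state an
interpolation rule) is averaged with the next strictly larger value; cells
strictly above the threshold are giant. The original pipeline's trained
SVM for stoma/pavement classification is replaced by a pluggable classifier
interface with a transparent default rule (stoma iff small and circular);
exact SVM replication is a non-goal.

# The growth simulator

Three variables per cell *i* evolve by chemical Langevin equations: the
transcription factor concentration A (constitutive production `P_A`, Hill
self-activation `V_A, K_A, n_A`, linear degradation `G_A`), its target T
(Hill activation by A, degradation `G_T`), and a division Timer (constant
production `P_C`). Each equation's noise term has amplitude
`c0 * sqrt(sum(|deterministic terms|) / eps_i)` with `eps_i = E0 * E_i(t)`
the effective cell size; integration is Heun predictor–corrector under the
Itô convention (noise coefficients evaluated at the step's start state),
`dt = 0.1`, negatives clamped to zero. The printed form of the noise
prefactor is corrupted in the available source; the standard
chemical-Langevin form above with a tunable constant `c0` is adopted, and
`c0` is a calibration knob.

Cell cycle: when the Timer crosses `theta_CS` the cell performs S-phase
(ploidy doubles, once per cycle); a post-S cell whose T exceeds `theta_T`
commits to endoreduplication — an absorbing state; at `theta_CD` committed
cells reset their Timer to U[0, 0.5) and continue endocycling while
uncommitted cells divide by the shortest wall through the cell centroid
(1° angular scan, ties broken by an RNG draw), daughters inheriting the
mother's A and T concentrations, drawing independent U[0, 0.5) Timers and
returning to 2C. Growth is kinematic: vertices displace exponentially from
the fixed tissue center of mass with rates `k_radial` (x) and `k_axial`
(y), and concentrations are multiplied by the per-cell area ratio
(dilution). Mechanics are prescribed, not force-based. The initial template
is a jittered-hexagonal bounded Voronoi patch (the original template is
unavailable); initial A ~ U[0,1), T ~ U[0,0.1), Timer proportional to the
within-template area rank with ±10% noise.

Numerical guards, documented deliberately: the noise amplitude uses
`eps_floor` (default: the initial mean cell area) as a lower bound on the
effective size — the chemical Langevin approximation degrades as system
size vanishes, and without the floor transiently small cells enter a
runaway (more noise → faster Timer → earlier division → smaller cells);
and cells below `min_div_area` postpone division until grown (a size
checkpoint, standard in cell-cycle models). Timer dilution is exempted by
default (`dilute_timer = FALSE`): diluting the Timer couples the division
clock to the growth rate and stalls cycling near the production/dilution
balance, producing small cells of high ploidy that have no biological
counterpart; the flag restores the literal reading.

The published parameter table for the reference model is not available in
the extracted sources, so defaults were calibrated (procedure in
`scripts/calibrate.R`, values in `inst/params/default_params.yaml`)
against two qualitative targets: fluctuation-driven A with rare excursions
to a high state (monostable-excitable or weakly bistable regime around the
shipped `V_A`, `K_A`), and on the order of 8 cells of ploidy ≥ 16C per
cropped tissue at `t_end = 135` among a few hundred cells. Giant cells in
simulated tissue are defined by the size-threshold rule: the threshold is
the minimum area among interior cells of ploidy ≥ 16C (border-clipped
cells are excluded from the threshold computation because the crop
truncates their areas), and every cell at or above it is giant — including
the few 8C cells that exceed it. Because commitment is stochastic, an
occasional replicate commits a small cell late and degrades the size
separation; the rule is applied as stated rather than patched, and the
pooled test absorbs such replicates.

# What the acceptance checks establish

* Planted-random patterns pushed through the full pipeline give p-values
  consistent with the exchangeable reference distribution (two-sample test
  at α = 0.01 over 200 generator seeds) — the null model is calibrated.
* Planted clumps (strong boost limit) are detected at p < 0.05 in ≥ 95% of
  seeds — the test has power against the alternative it is meant for.
* Simulated tissues at `t_end` show significantly more giant neighbors per
  giant than their randomizations (pooled over 5 replicates, 100
  randomizations each — a scaled-down ensemble; the qualitative rejection,
  not the exact p, is the claim).
* First-arising giants (committed by `t_select = 55`) are mostly
  non-significant at t = 55 but the same cells become significant by
  t = 135 under whole-tissue randomization in most runs: contacts between
  non-dividing cells persist while the surrounding tissue proliferates, so
  the same arrangement becomes increasingly unlikely under the null.
* All fast-path computations agree exactly with independent oracles
  (pixel-pair adjacency scan, union-find components, sorted-sample
  Wasserstein, classical-MDS eigendecomposition, dense angular chord scan),
  and the noise-free simulator matches an independent RK4 integration to
  relative error < 1e-3 over the full time span.

# Known limitations

* The randomization engine is a reconstruction of an unpublished method;
  its artifact profile is similar in kind but not bit-compatible.
* Pavement-cell lobes, basipetal developmental gradients, and 2.5-D
  curvature are not modeled; the generator's cells are convex-ish.
* The simulator's parameterization is a calibrated stand-in, not the
  published table; quantities that depend on absolute rates (cycle times,
  ploidy histograms) should be read qualitatively.
* `visibility` uses a deterministic contour subsampling because the
  feature's sampling scheme is only described verbally in the field;
  values are comparable within this package only.
* The permutation scheme of the original Wasserstein test is unnamed in
  the source; a plain label-permutation test with add-one smoothing is
  used here.
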