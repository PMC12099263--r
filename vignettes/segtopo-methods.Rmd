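---
title: "Evaluating multi-class 3D segmentations with overlap, boundary, volume and topology metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating multi-class 3D segmentations with overlap, boundary, volume and topology metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segtopo)
```

## Scope and model

`segtopo` evaluates pairs of multi-class 3D label maps — a manually
annotated ground truth and an automatic prediction — the way multi-team
segmentation studies of the fetal brain are evaluated: per-tissue
metrics, anatomically informed topology checks, and a leaderboard built
by mean-then-rank aggregation. The unit of evaluation is a `label_map`:
a voxel grid of integer codes, a physical voxel spacing in mm, and a
label dictionary. The default dictionary encodes the eight-class fetal
scheme (0 = background, 1 = eCSF, 2 = cortical grey matter, 3 = white
matter, 4 = ventricles, 5 = cerebellum, 6 = deep grey matter,
7 = brainstem), but every function works through the dictionary, so any
coding scheme can be configured via YAML.

Three design commitments run through the package:

* **No silent geometry changes.** Spacing always comes from the NIfTI
  header; ground truth and prediction must share a voxel grid, and a
  shape mismatch is a hard error rather than a resample, because
  resampling would corrupt every metric downstream.
* **Bit-reproducibility.** Every stochastic step (bootstrap, phantom
  generation, defect placement) is driven by an explicit seed recorded
  in the outputs.
* **Exactness where exactness is checkable.** The distance transform is
  exact, percentiles follow a documented convention, and the topology
  pipeline is validated against an independent algebraic reference
  implementation shipped in the package.

## Per-tissue metrics

For each (case, tissue) pair with ground-truth mask $A$ and predicted
mask $B$:

* **Dice similarity coefficient** $\mathrm{DSC} = 2|A \cap B| / (|A| + |B|)$,
  the standard overlap measure.
* **Volumetric similarity** $\mathrm{VS} = 1 - \frac{\,||A| - |B||\,}{|A| + |B|}$,
  which compares total volumes regardless of overlap — relevant because
  tissue volumes are used directly as clinical biomarkers. For any pair,
  $\mathrm{VS} \ge \mathrm{DSC}$.
* **95th-percentile Hausdorff distance (HD95)**, in mm. Border voxels of
  each mask are those with at least one face neighbour outside the mask
  (the domain boundary counts as outside). Each border voxel of one mask
  is paired with the Euclidean distance to the nearest border voxel of
  the other mask, computed with an exact anisotropic distance transform
  (Felzenszwalb–Huttenlocher), so the result equals the brute-force
  minimum over all border pairs. HD95 is the maximum over the two
  directions of the 95th percentile of that direction's distance
  multiset — the "robust Hausdorff" convention.

Numerical choices worth stating because they silently differ between
tools:

* **Percentile rule.** Linear interpolation between order statistics
  (`stats::quantile` type 7, the same as NumPy's default). With a fixed
  rule, HD95 is bit-reproducible; setting the percentile to 100 recovers
  the exact symmetric Hausdorff distance.
* **Surface representation.** Border voxel *centres* under a
  6-connectivity exterior test, rather than the surfel midpoints some
  tools use. The discrepancy between the two conventions is bounded by
  one voxel diagonal; voxel centres were chosen because they admit an
  exact brute-force oracle, which the test suite exercises to 1e-9.
* **Degenerate inputs.** A tissue empty in both maps has no defined
  overlap; such cells are excluded from ranking means with a warning. A
  tissue empty only in the prediction takes the missing-label penalty
  path described below. Distances to an empty surface are an error, not
  a zero.

## Topology: Betti numbers and the Betti number error

Downstream analyses of cortical segmentations (thickness, gyrification)
require topologically correct masks, yet overlap metrics barely notice a
severed cortical ribbon or a tunnel through the white matter. The
package therefore quantifies topology through the first three Betti
numbers of each binary mask: $b_0$ connected components, $b_1$ tunnels,
$b_2$ enclosed cavities.

Conventions (each of these is a genuine choice; digital topology is
paradox-prone when they are mixed carelessly):

* Foreground connectivity 26, background connectivity 6 — the standard
  dual pairing, consistent with treating each foreground voxel as a
  closed unit cube.
* $b_2$ counts bounded components of the background under
  6-connectivity after padding the mask with a one-voxel background
  shell, so structures touching the canvas edge cannot create spurious
  cavities.
* $b_1$ is not computed by loop detection. Instead the Euler
  characteristic $\chi = V - E + F - C$ is counted directly from the
  distinct vertices, edges, faces and cubes of the voxel cubes' union,
  and $b_1 = b_0 + b_2 - \chi$, which is exact for this complex.
* Betti numbers are invariant under translation and padding, so they
  are computed on the foreground bounding box for speed.

Correctness of this fast path is established against an independent
reference implementation, `betti_numbers_gf2()`, which assembles the
full cubical chain complex and computes boundary-matrix ranks over
GF(2) ($b_k = \mathrm{nullity}\,\partial_k - \mathrm{rank}\,\partial_{k+1}$).
The two routes share no code beyond mask handling; the test suite
checks exact agreement on thousands of random masks up to $6^3$ plus
canonical solids, shells and rings.

The **Betti number error** $\mathrm{BNE}_k$ is the absolute difference
between a predicted mask's $b_k$ and the anatomically expected value.
The default expectation table says every tissue should be a single
handle-free, cavity-free component, except the cortical grey matter,
whose left and right hemispheric ribbons make $b_0 = 2$ (a perfect GM
score is 2/0/0). The table is configuration, not code, because the
GM value is specific to this annotation scheme.

## Ranking

The ranking engine turns the per-(team, case, tissue) score table into
leaderboards:

1. **Missing-label penalties.** If a tissue present in the ground truth
   is absent from a team's prediction, that cell gets the worst possible
   values: DSC and VS of 0, HD95 equal to twice the maximum HD95
   observed for that tissue among all non-missing submissions, and
   $\mathrm{BNE}_k$ equal to twice the worst observed error. The penalty
   pool is per label across the whole cohort by default; a per-case
   variant is available (`scope = "label_case"`). Filling a cell this
   way can never improve a team's mean — a property the tests assert.
2. **Mean-then-rank per metric.** Each team's values are averaged over
   all (label, case) cells (pooled mean; a per-label-then-average option
   exists) and teams are ranked in the metric's direction. Tied means
   receive fractional ranks (mean of tied positions).
3. **Aggregation.** The final rank is the rank of the mean of the three
   per-metric ranks — the simplest combiner that weights the overlap,
   boundary and volume families equally. Published rankings render ties
   as shared positions with the next rank skipped; fractional ranks are
   used whenever a ranking feeds a further mean.
4. **BNE and TIR.** Teams are ranked per topological dimension by mean
   $\mathrm{BNE}_k$; the overall BNE rank averages the three
   per-dimension ranks by default (`method = "rank"`; ranking the mean
   BNE values is available as `method = "value"` since either reading
   is defensible). The topology-integrative ranking (TIR) then averages
   the DSC, HD95, VS and overall-BNE ranks with equal weight. Because
   topology enters only here, a team with excellent overlap but a
   severed, punctured segmentation keeps its aggregate position and
   drops only in the TIR — exactly the behaviour the synthetic
   mini-challenge demonstrates.
5. **Per-label and subset rankings** re-run the same aggregation on one
   tissue or one metadata stratum (site, quality rating 1–3, pathology
   flag, reconstruction method).
6. **Stability and significance.** Case-level bootstrap (default 1000
   replicates, seeded) yields each team's rank distribution; pairwise
   one-sided Wilcoxon signed-rank tests on per-case means, Holm-adjusted
   per row, mark which orderings are statistically meaningful. Pairs
   with fewer than five paired cases are marked untestable, and
   identical score profiles yield p = 1 by convention.

## The synthetic phantom

All of the above is exercised end-to-end without any imaging data by a
phantom generator whose outputs are *correct by construction* with
respect to the expected-topology table — which makes every generated
ground truth a nontrivial test vector for the topology module itself.

The geometry is a nested-sphere caricature of the fetal brain on a
$64^3$ canvas at 0.5 mm spacing (256³ is supported for realism; 64³
keeps routine runs in seconds): an eCSF shell, a GM ribbon split into
two hemispheres by a mid-sagittal gap of at least two voxels (one-voxel
gaps can be bridged diagonally under 26-connectivity), a solid WM ball,
and four interior structures carved from the WM. Two shapes require
care to avoid accidental topology: the eCSF shell has a polar plug
removed (a closed shell would enclose a cavity), and every interior
structure is connected to the background through a thin channel running
inside the sagittal gap (otherwise each would leave a cavity in the
WM). Cohort cases jitter the radii and blob offsets by ±4%.

Corruption profiles then emulate prediction error modes with verifiable
effects: morphological dilation/erosion by a per-label radius (graded
boundary error; mean Dice decreases monotonically with radius),
translation jitter (metric error with *preserved* topology — useful as
a control), planar cuts through the GM ribbon (each adds at least one
spurious component, emulating the discontinuous cortical segmentations
seen in practice), tunnels drilled through and cavities injected into
the WM (raising $b_1$ and, exactly one per cavity, $b_2$), and dropped
labels (triggering the penalty path).

What the phantom does *not* emulate: intensity images and their
artifacts, realistic cortical folding, gestational-age-specific
anatomy, inter-rater annotation noise, or anisotropic acquisition
grids. Passing the phantom suites therefore demonstrates that the
*evaluation machinery* is correct and discriminative — not that any
particular segmentation algorithm performs well on real data.

The default five-team panel (`default_team_profiles()`) is engineered
so the ranking engine's contracts are all visible in one run: an
identity team that must win everything, two jitter teams that are
metrically degraded but topologically clean, a topology-sloppy team
whose overlap is nearly perfect, and a team that drops the brainstem
entirely. On this panel the sloppy team outranks the jitter teams in
the three-metric aggregate but falls behind in the TIR.

## Problem sizes and runtime choices

Routine verification runs at desk scale: phantoms at $64^3$ (48³ for
the file-based pipeline tests), cohorts of 10 cases × 5 teams, 1000
bootstrap replicates, 2000 random masks (up to $6^3$) against the GF(2)
oracle and brute-force distance oracles on $4^3$ batches. These sizes
were chosen so the whole suite completes in minutes on a single core
while still exercising every code path at full numerical strictness;
nothing in the implementation is specific to them, and the canvas size,
cohort size and replicate counts all scale by configuration.

## Known limitations

* HD95 assumes both masks live on a common voxel grid; evaluating
  predictions produced at a different resolution requires resampling
  *before* evaluation, a step this package deliberately refuses to do
  implicitly.
* The GF(2) reference path is cubic in the cell count and intended for
  small masks only; it is a correctness oracle, not a production path.
* The Wilcoxon significance tests treat cases as exchangeable; they do
  not model site clustering.
* Betti numbers summarise topology globally — they locate neither the
  defect nor its size, and the BNE cannot distinguish one large gap
  from one small one.
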