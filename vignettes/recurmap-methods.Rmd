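---
title: "Methods: target-volume reconstruction, six-region classification, and cohort statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: target-volume reconstruction, six-region classification, and cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(recurmap)
```

# Overview

`recurmap` quantifies where contrast-enhancing glioblastoma recurrence
sits relative to radiotherapy target volumes reconstructed from the
post-operative resection cavity. This vignette documents the model, its
assumptions, the numerical choices behind the implementation, what the
synthetic phantom generator does and does not emulate, and the design
decisions taken where the problem was genuinely open.

# Geometry

## Coordinate conventions

All per-case volumes must share one grid; the pipeline never resamples,
because resampling changes absolute voxel counts — the analysis' unit of
measure. Voxel indices are 0-based internally; the center of voxel
$(i, j, k)$ sits at $(i s_x, j s_y, k s_z)$ millimetres, where $s$ is
the (possibly anisotropic) spacing from the NIfTI header. A voxel
belongs to a region iff its *center* does. Distances are always
Euclidean in millimetres. The header affine is carried through I/O and
compared across volumes (tolerance $10^{-3}$ elementwise; spacing
$10^{-4}$ mm per axis) but plays no role in the internal geometry.

## The analysis CTV: rasterized convex hull

The clinical target volume is reconstructed as the convex hull of the
cavity voxel centers: a voxel is in the CTV iff its center lies inside
or on the hull. Full-rank point sets go through an incremental
quickhull; the facet half-spaces (unit normals) then classify every
candidate center within the cavity's bounding box, with an absolute
tolerance of $10^{-7}$ mm so that centers lying exactly on a facet are
counted inside. On a lattice this tolerance is safe: a lattice point not
on a facet plane through lattice points is at least on the order of
$10^{-3}$ mm away from it.

Voxel-center containment (rather than any-corner) was chosen because it
is unambiguous and matches voxel counting. Two consequences follow and
are verified as properties: the hull contains its input, and re-hulling
is idempotent (the rasterized hull's extreme points are the original
cavity's).

Degenerate cavities — single voxel, collinear, coplanar — have no
full-rank hull. They are rasterized by distance to the
lower-dimensional hull (point, segment, or planar polygon, via SVD rank
detection) with a half-voxel tolerance (half the smallest spacing). For
lattice-aligned degenerate sets this coincides with exact on-hull
membership.

No anatomical cropping is applied by default: the reconstructed hull
deliberately extends beyond barriers such as the skull or falx, because
margin reduction at anatomical boundaries is a planning-system concept
the analysis intentionally omits. An optional brain mask intersects the
CTV/PTV when supplied.

## The analysis PTV: concentric expansion

The PTV is the closed Euclidean dilation
$\{v : d(v, \mathrm{CTV}) \le m\}$ with $m = 5$ mm by default,
computed with a separable lower-envelope (parabola) squared distance
transform generalized to anisotropic sample spacing. The ball is closed
so that a zero margin is the identity. Comparisons are made on squared
distances with an additive guard of $10^{-9}$ mm²; for integer-valued
spacings all squared distances are exactly representable, so results
are exact, and the expansion is monotone in the margin.

The 5 mm physical margin (not a fixed voxel dilation) was chosen so the
construction is spacing-independent; both the margin and the choice are
exposed in the configuration.

## Reference implementations

Two exhaustive oracles ship in the package and are exercised by the
test suite against the production paths, voxel for voxel:

- `referenceHullMask()` enumerates all supporting planes spanned by
  triples of (midpoint-reduced) foreground centers — an exact
  point-in-hull test that shares no code or algorithm with quickhull.
  Midpoint reduction removes only provably non-extreme lattice points
  (those that are midpoints of two foreground neighbours along any of
  the 13 lattice directions), leaving the hull unchanged.
- `referenceExpandMask()` thresholds exhaustive nearest-point
  distances.

They scale poorly by design; the suite runs them on grids up to
$25^3$.

# Six-region classification

Enhancing voxels at progression are partitioned against the target
volumes: inside CTV, outside CTV, the CTV–PTV transition zone
($\mathrm{PTV} \setminus \mathrm{CTV}$), outside PTV, and the
perfusion inclusion zone (IZ) split by CTV side. The counts satisfy,
structurally: inside + outside = total; transition + outside-PTV =
outside; IZ counts bounded by their parent regions. Every emitted row
is validated against these identities before being written.

## The inclusion zone

How perfusion imaging became a binary "metabolically active" zone is a
genuinely open point; the package's definition is an explicit stand-in:
a voxel is in the IZ iff it is enhancing *and* its relative CBV is at
least `iz_threshold_ratio` (default 1.75, a conventional rCBV cutoff
for active tumor) times the mean rCBV over a user-supplied
normal-tissue reference mask (typically contralateral normal-appearing
white matter). Restricting the IZ to enhancing voxels makes regions
3–4 sub-counts of regions 1–2. A pre-made IZ mask can be used instead
by bypassing `deriveInclusionZone()`. The reference mean must be
positive; an empty reference is an error, an empty IZ is legal and
logged.

## Distance bands

Each enhancing voxel's distance to the CTV *voxel set* (zero on or
inside the CTV — unsigned, which keeps the bands a partition) is binned
at cuts of 20 and 30 mm, closed on the left band (≤ 2 cm, 2–3 cm,
> 3 cm). Whether inside-CTV voxels belong in the first band's
denominator is ambiguous in principle; they are included by default
(`include_inside_in_bands = TRUE`) and the choice is configurable. Band
edges compare squared distances exactly, so a voxel at exactly 25 mm
falls in the middle band deterministically.

# Cohort statistics

- **Test selection.** For each region, Shapiro–Wilk is applied to both
  group samples; Welch's t test is used iff both have
  $p \ge \alpha$ (default 0.05), otherwise the Mann–Whitney U test.
  Constant samples (Shapiro–Wilk undefined) route to Mann–Whitney. All
  tests are two-sided — the analysis reports p-value magnitudes
  consistent with that convention.
- **Mann–Whitney paths.** Exact null distribution when both $n \le 8$
  and the pooled sample is tie-free; tie-corrected normal approximation
  with continuity correction otherwise. The exact path is verified
  against full permutation enumeration to machine precision; the two
  paths agree within 0.05 for $n = 8 + 8$ tie-free samples.
- **Summaries.** Medians and IQRs (q1–q3) use linear interpolation
  (quantile type 7), the common default.
- **Categorical covariates.** Pearson chi-squared without continuity
  correction; `"unknown"` levels are dropped by default. A zero
  marginal row/column is an error.
- **Survival.** Kaplan–Meier medians per group with non-progressed
  cases censored at their recorded follow-up, progression proportion as
  $100 \cdot \text{events}/n$ rounded to one decimal, and a log-rank
  test between groups (an assumption: no specific test is canonical
  here). On degenerate inputs whose log-rank variance is singular, the
  p-value is reported as `NA` rather than failing.
- **Multiplicity.** No multiple-testing correction is applied by
  default, matching the convention of reporting per-region and
  per-subgroup p-values raw; `compareAllRegions(adjust = "BH")`
  provides Benjamini–Hochberg when wanted.

# The synthetic phantom generator

## What it emulates

Each phantom is a spherical resection cavity plus spherical recurrence
components placed at signed offsets from the CTV surface along random
directions: one component inside the cavity (in-field recurrence), one
centred 2.5 mm beyond the surface (transition-zone burden), one at
8–32 mm (out-of-PTV burden spread across the distance bands). A CBV
channel holds 1.0 everywhere and 3.0 on a per-component random active
subset, with a reference ball placed in a quiet corner — so the default
1.75 threshold recovers exactly the active subset. Cohorts draw
per-region burdens (mm³) log-normally, with per-group multiplicative
effects on the expected burdens; covariates are i.i.d. from specified
frequencies and PFS follows a per-group model (below).

Default template, chosen once as plausible study conditions: $96^3$
voxels at 2 mm isotropic (a realistic head field of view); cavity radii
uniform on 18–26 mm; photon-like burden medians 25 000 / 1 250 /
2 200 mm³ (inside / transition / outside-PTV) with proton-like effects
0.76 / 9.5 / 8.7 — giving out-of-CTV group medians of order $10^3$
versus $10^2$ voxels, the dynamic range such cohorts exhibit, with no
claim to reproduce any specific cohort's numbers; group sizes 94 and
50; progression probabilities 0.84 / 0.80; group KM medians 9.56 /
6.77 months.

## Ground truth

`makePhantomCase()` returns, with each case, a region-count row
computed *only* from the spec geometry by exact per-voxel tests:
because a Euclidean ball is convex, the lattice points it contains are
digitally convex (the convex hull of the cavity's voxel centers,
intersected with the lattice, is the cavity itself), so ground-truth
CTV membership is analytic ball membership; PTV membership and band
distances come from exhaustive nearest-point search. This route shares
nothing with the quickhull/distance-transform pipeline, and the suite
requires exact equality between the two on randomized phantoms.

## PFS model

Progression is Bernoulli per group; event times are exponential. A
mixture like this has a cohort KM median *above* the event-time
median, so the `median` parameter of `cohortSpec()` is defined as the
group-level KM median and the event-time rate is solved from
$S(m) = (1-p) + p e^{-\lambda m} = 1/2$ (falling back to
$\lambda = \ln 2 / m$ if $p \le 0.5$, where the cohort median is
undefined). Non-progressed cases are censored uniformly at 6–36 months.

## What it does not emulate

No MRI intensities, lesion texture, mass effect, segmentation error,
or registration error: components are exact spheres on a shared grid.
Passing tests therefore demonstrate correctness of the geometry,
classification and statistics on well-posed inputs — not robustness to
segmentation noise or inter-scanner grid differences. Real cohorts mix
field strengths and grids; because counts are grid-dependent, the
pipeline also reports the voxel volume (mm³) with every row so users
can convert counts to physical volumes.

## Determinism

One master seed determines a cohort; per-case streams are derived from
the seed and the case *index*, so case $k$ is identical whether the
cohort has 6 or 144 cases. The generator saves and restores the global
RNG state.

# Statistical calibration of the suite

The test suite checks, at fixed seeds: type-I error of the outside-CTV
comparison on 1 000 null burden cohorts ($n = 30 + 30$) within
$5\% \pm 2\%$; power $\ge 90\%$ against a tenfold transition-zone
effect ($n = 40 + 40$, 200 cohorts); and stratum specificity (an
effect confined to one covariate stratum is detected there and not in
the complement). Calibration and power run on the generator's burden
tables — the layer of the generator that defines the ground-truth
count distributions — because they measure properties of the test
battery, not of the rasterizer; the rasterized path is covered by the
exact ground-truth equivalence and partition-invariant checks
(200 + 100 randomized phantoms on grids of $28^3$–$36^3$ at 2 mm,
sizes chosen to exercise full geometry while keeping the suite quick).

# Known limitations

- The hull is built from all foreground centers; pathological masks
  with very large voxel counts are handled (quickhull is near-linear
  here) but the exhaustive reference implementations are not intended
  for them.
- The IZ definition is a stand-in for an unspecified clinical
  procedure; results involving regions 3–4 inherit that assumption.
- Counts are native-grid counts; cross-scanner comparability requires
  either a shared grid or conversion to mm³.
- The photon arm's clinically used 2 cm CTV margin is *not* used for
  analysis geometry: both groups are analysed with the same hull +
  5 mm construction, deliberately, so that between-group differences
  are not artifacts of different reconstructions.
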