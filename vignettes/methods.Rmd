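---
title: "Methods: laterality quotients, connectometry and tract shape analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: laterality quotients, connectometry and tract shape analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latconn)
```

# The problem

Whether language is supported predominantly by the left hemisphere, the
right, or both varies across healthy people. Two structural questions follow:
does the microstructure of white matter (its anisotropy) co-vary with the
degree of functional lateralization, and does the geometry of the major
language bundles (their length, curvature, volume) differ between dominance
groups? `latconn` implements a complete, testable pipeline for both
questions: a functional laterality quotient computed from task-fMRI
activation maps in grayordinate space, correlational connectometry over
tract-segment anisotropy, bundle shape metrics, and the group statistics that
tie them together. A seeded synthetic-cohort generator stands in for imaging
data so that every stage can be validated against known ground truth.

# The laterality quotient

For each subject and ROI family (frontal: Brodmann areas 44/45; temporal:
TGd, TGv, TE1a, TE2a, STGa, STSva, STSda), activation z values are:

1. **Thresholded per ROI** at the within-subject median — only grayordinates
   with z strictly greater than their own ROI's median are retained. With an
   even count the median is the midpoint of the two central values; an ROI
   whose values are all equal retains nothing.
2. **Summed and normalized per hemisphere** — the retained z values of all
   ROIs in one hemisphere are summed and divided by that hemisphere's total
   *pre-threshold* grayordinate count. Grayordinate space carries roughly 100
   more surface vertices on the left than the right; dividing by the
   pre-threshold count is what corrects this size imbalance (dividing by the
   retained count would cancel the thresholding instead, which is why the
   denominator is configurable but defaults to `"all"`).
3. **Combined into the quotient** `LQ = (L − R) / max(L, R)`, a
   Jaccard–Tanimoto-style distance in `[−1, 1]`. Values strictly above +1/3
   are classified left language dominant (LLD), strictly below −1/3 right
   dominant (RLD), and everything in between — including the boundaries
   themselves — bilateral (BLR). Reading "above/below" strictly makes the
   boundary convention explicit; the thirds give equal cumulative probability
   under a uniform LQ.

Two exact invariances follow from the construction and are enforced by
property tests: swapping the hemisphere labels negates LQ, and multiplying
all z values by a positive constant leaves it unchanged (the median threshold
and the count normalization are both equivariant). Negative normalized
activations are possible in principle when z sums are negative; the pipeline
proceeds as long as `max(L, R) > 0` and flags such subjects
(`flag_negative`) rather than guessing a convention.

# Synthetic activation cohorts

`gen_activation_cohort()` draws each hemisphere a positive base pattern
(`1 + |N(0,1)|` per grayordinate, split across the ROI labels) and rescales
the two hemispheres by closed-form constants so that the full
threshold → normalize → LQ pipeline returns the subject's target LQ exactly
at zero noise. Because the pipeline is scale-equivariant, this construction
is exact rather than fitted; Gaussian noise of standard deviation `noise_sd`
(z units) is added after scaling. Defaults are desk-scale: 1,000 left / 900
right grayordinates per ROI set, preserving the direction and approximate
size of the left–right imbalance at ~3% of full surface resolution (32,492
vertices per hemisphere). No published per-ROI z distributions exist for
this construction; the positive-Gaussian base pattern is a stipulated,
documented choice. The zero-noise recovery is exact to floating tolerance
(two divisions per hemisphere scale factor leave errors of order 1e−16).

What the generator does *not* emulate: spatial autocorrelation of activation
across the cortical surface, subject-level differences in overall activation
strength beyond a scale factor (which LQ ignores by construction), and
crossed frontal/temporal dominance within a subject (families are generated
independently). Passing tests therefore validate the algebra and the
estimator, not the spatial statistics of real fMRI maps.

# Correlational connectometry

The connectometry stage takes a subjects × segments matrix of quantitative
anisotropy (QA) plus per-segment geometry (position, orientation, physical
length, adjacency) and asks which contiguous chains of segments carry QA that
co-varies with the laterality quotient.

* **Statistic.** A nonparametric Spearman *partial* correlation: both the
  study variable and each segment's QA are rank-transformed (average ranks
  for ties), residualized on an intercept plus the covariates (handedness,
  sex, age by default), and correlated. Constant segments are flagged and
  excluded from selection. The per-segment T score is the partial-correlation
  t statistic, `t = ρ√((n−k−2)/(1−ρ²))` with `k` covariates — the standard
  conversion, stated explicitly because selection thresholds are quoted on
  the T scale.
* **Selection and growth.** Segments with `t ≥ +3` (or `≤ −3`) are marked and
  maximal same-sign connected chains are grown over the adjacency graph; a
  track's length is the sum of its member segments' physical lengths. The
  default threshold of 3 is deliberately conservative against false
  positives.
* **Pruning.** Topology-informed pruning is approximated by a support rule:
  every selected segment seeds a candidate track (its maximal chain), tracks
  containing any segment supported by only one track are removed, and support
  is recomputed until a fixed point or 16 iterations. In chain geometry this
  reduces to discarding isolated single-segment spurs while any
  multi-segment chain supports itself; duplicates then collapse to unique
  chains. This is an explicitly simplified surrogate for streamline-density
  based pruning — the density information it would use does not exist in the
  segment-matrix abstraction.
* **Permutation null and FDR.** The study variable is shuffled across
  subjects (5,000 permutations by default; covariate rows stay aligned with
  QA, preserving the nuisance structure) and the entire
  statistic → threshold → grow → prune pipeline is re-run, recording all null
  track lengths. For an observed length ℓ, the raw FDR is the mean
  per-permutation count of null tracks ≥ ℓ divided by the observed count
  ≥ ℓ, clipped to `[0, 1]`; a step-down running minimum makes the curve
  nonincreasing in ℓ (both curves are reported). Tracks significant at
  FDR ≤ 0.01 and at least 20 mm long are reported, per sign; FDR is
  estimated per sign (a pooled analysis can be run by merging the null and
  observed sets). Group contrasts (LLD vs BLR and the like) reuse the same
  machinery with a 0/1 indicator as the study variable on the subject
  subset.

Determinism: the permutation stream is seeded, and RNG state is saved and
restored around it, so `(matrix, covariates, config, seed)` fully determine
the output. Negating the study variable swaps the positive and negative
track sets exactly, a consequence of rank antisymmetry that the tests
enforce.

## Synthetic connectomes

`gen_local_connectome()` builds the QA matrix over a 1-D chain of segments
(uniform 2 mm each — the simplest geometry in which "track length" and the
20 mm filter are meaningful, and matching the 2 mm working resolution of the
shape stage). A latent standard normal `u` drives the laterality quotient
(`LQ = tanh(0.6·u)` by default, or the normal scores of user-supplied LQs);
inside the planted block the QA latent loads on `u` with coefficient
`a = r√(1+v)` where `v` is the variance contributed by the standardized
covariate confound, making the population correlation between QA latent and
`u` equal to the requested `effect_r` despite the confounding. QA itself is
`0.3·exp(0.15·latent)` — strictly positive and monotone in the latent, so
rank-based targets survive the transform (Spearman's ρ of a bivariate normal
is `(6/π)·asin(r/2)`, within 0.01–0.02 of `r` over the range used).
Covariates mirror a young-adult cohort: age uniform on 22–35, sex
Bernoulli(0.5), Edinburgh handedness concentrated near +100 with an ~8%
left-handed minority.

Under the null (`effect_r = 0`) the per-segment two-sided tail probability at
`|t| ≥ 3` is ≈ 0.003, so a 300-segment null cohort carries on average under
one marked segment per sign; isolated marks are pruned, and chains of the
ten consecutive segments needed to pass 20 mm essentially never occur — the
measured fraction of null cohorts with any significant track is far below
the nominal 0.01. The calibration test fixes 50 cohorts of 200 subjects, 300
segments and 200 permutations, sizes chosen to finish in seconds while
leaving binomial headroom (at a true rate of 0.01, more than 2 hits in 50
cohorts has probability < 2%).

# Shape metrics

Seven metrics per bundle, using the equivalent-cylinder definitions (the
field's standard shape-descriptor set; the quantities are named in published
figures but their formulas are rarely printed, so they are fixed here
explicitly):

| metric | definition |
|---|---|
| mean length | mean over streamlines of polyline arc length |
| span | mean over streamlines of endpoint distance |
| curl | mean length / span |
| diameter | `2√(volume/(π·mean length))` |
| elongation | mean length / diameter |
| volume | occupied-voxel count × voxel³ |
| surface area | exposed voxel faces × voxel² |

Span and curl are computed per streamline and averaged (rather than as a
ratio of means); this preserves `curl ≥ 1` streamline-wise, since every arc
is at least as long as its chord. `elongation·diameter = mean length` holds
as an algebraic identity and is asserted in tests. Voxelization marks every
voxel containing at least one streamline point after supersampling each
segment at half-voxel steps; the grid origin is the floor of the bounding
box, making counts reproducible; the default resolution is 2 mm isotropic.
Point-membership voxelization is deterministic and simple, at the cost of a
quantified staircase bias: on the calibration cylinder (radius 4 mm, length
100 mm, 1 mm voxels, deterministic grid fill) volume is within ~5% of
`πr²L` and diameter within ~3% of the true 8 mm, while surface area
overshoots the analytic `2πrL + 2πr²` by ~28% — the Manhattan perimeter of
a digital disk exceeds the circumference by up to 4/π. Surface area is
therefore comparable *between* bundles voxelized the same way, not an
unbiased estimate of the smooth-surface area, and the tests bound its error
at the measured 30% rather than pretending better.

The bundle generator produces straight, circular-arc and helical centerlines
with analytically known length, span and curl (semicircle: curl = π/2),
offset copies within a tube radius, and optional per-point jitter. For
volume fixtures a deterministic `grid` layout fills the tube cross-section
at a chosen spacing: with random offsets at realistic streamline counts,
boundary voxels are hit in proportion to arrival probability rather than
intersection area, inflating voxel counts; a regular fill keeps the occupied
count at the lattice-point count of the disk, within a few percent of the
analytic cross-section.

Out of scope by design: fiber tracking, bundle recognition against an atlas,
and trunk/branch sub-volumes (no parcellation rule is defined for the
bundles consumed here); bundles arrive as already-tracked TCK/TRK files or
generator output.

# Group statistics

`anova_by_group()` tests a shape metric across dominance groups after
covariate adjustment, as a type-II extra-sum-of-squares F test (group term
on top of the covariate-only model); with no covariates it reduces to the
classical one-way ANOVA, and with two groups `F = t²` exactly. Groups with
fewer than two members are excluded with a warning rather than an error —
right-dominant groups are routinely this small. Tukey HSD provides the
pairwise post hoc comparisons, and Benjamini–Hochberg controls the FDR over
the family of metrics tested in one call (the family is whatever one
`compare_shape_by_laterality()` call covers, declared in the run manifest;
"FDR corrected" without a named method is taken as BH, the default choice in
this literature). `regress_lq_on_feature()` is the ordinary least-squares
complement for continuous structural features. The implementations delegate
to R's `lm`/`aov`/`TukeyHSD`/`p.adjust`; the test suite verifies them
against independently coded normal-equations, studentized-range and hand-BH
oracles to 1e−8.

# The pipeline and its files

`run_pipeline()` chains simulate → laterality → connectometry → shape →
group statistics for one ROI family and writes: the grayordinate table and
laterality TSV, the connectome CSV + JSON sidecar, segment statistics, track
and FDR tables, per-subject shape metrics, group tests, the LQ regression,
and a JSON manifest recording the package version, full configuration, seed
and input hashes — but no timestamps, so a rerun with the same seed is
byte-identical. The default simulated cohort is 100 subjects with LQ targets
drawn from the frontal cohort distribution N(0.33, 0.31) truncated to
(−1, 1) (temporal: N(0.17, 0.20)), a planted negative QA–LQ block
(`effect_r = −0.4`, mirroring the sign of commissural findings), and a
+6 mm tract-length shift for left-dominant subjects so the group statistics
have a real effect to find.

Problem sizes used by the test suite and the acceptance script — chosen as
desk-scale study conditions with known ground truth — are: 19-subject
zero-noise and 50-subject noisy laterality cohorts; 50 null-calibration
cohorts (200 subjects × 300 segments, 200 permutations); planted-effect runs
of 300 subjects × 300 segments with 500 permutations; and a 100-subject
end-to-end pipeline. Production analyses would raise `n_permutations` to the
5,000 default.

# Numerical choices and known limitations

* Median threshold is strict (`>`); boundary LQ values ±1/3 classify as BLR.
* Ties in ranks use average ranks everywhere; degenerate (constant) segments
  are excluded from selection and reported as `NA`.
* `t_from_r` at |ρ| = 1 returns a signed infinity sentinel rather than an
  error, so a perfectly monotone segment is selected, not dropped.
* The FDR curve is reported both raw and after the step-down running
  minimum; significance uses the monotone curve.
* TRK files store voxel-mm coordinates; reading applies the header's
  voxel-to-world affine under the voxel-center convention, and version-1
  files without an affine fall back to voxel-size scaling.
* The pruning rule and the 1-D chain adjacency are simplified surrogates for
  streamline-level topology and 3-D fiber geometry; results on real local
  connectome matrices require mapping their fiber-orientation adjacency onto
  the segment graph, which is out of scope here.
* Twin/family structure is ignored in the group statistics (no mixed
  effects), matching the analysis design this package reproduces.
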