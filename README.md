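# latconn

Tools for relating white matter microstructure and tract geometry to
hemispheric language dominance. The package implements, as one reusable and
fully tested chain:

* **Laterality quotients (LQ)** from task-fMRI activation z maps in
  grayordinate space — per-ROI median thresholding, hemisphere-size
  normalization, and the Jaccard–Tanimoto-style quotient
  `LQ = (L − R) / max(L, R)` with the ±1/3 three-way classification into
  left-dominant (LLD), bilateral (BLR) and right-dominant (RLD) subjects.
* **Correlational connectometry** over subject × tract-segment quantitative
  anisotropy (QA): covariate-adjusted Spearman partial correlation
  (handedness, sex, age), T-score thresholding at 3, contiguous track
  growing over the segment adjacency, topology-style pruning, a permutation
  null over track length (5,000 permutations by default), FDR control at
  0.01 and a 20 mm minimum track length.
* **Bundle shape metrics** from TCK/TRK streamline files or synthetic
  bundles: mean length, span, curl, elongation, equivalent-cylinder
  diameter, voxelized volume and surface area at 2 mm resolution.
* **Group statistics**: covariate-adjusted ANOVA of shape metrics across
  laterality groups, Tukey HSD post hoc tests, Benjamini–Hochberg FDR, and
  linear regression of LQ on structural features.
* **Synthetic cohorts** with known ground truth (target LQs recovered
  exactly at zero noise, bundles with analytic geometry, QA matrices with a
  planted, covariate-confounded correlation block), so the entire pipeline
  runs and is validated without any imaging data.

## Worked example

```r
library(latconn)

# a 12-subject cohort with known laterality targets, frontal ROIs (BA44/45)
rs <- roi_set("frontal")
targets <- seq(-0.9, 0.9, length.out = 12)
cohort <- gen_activation_cohort(
  cohort_spec(12, targets, noise_sd = 0.1, seed = 42), rs)
lat <- run_laterality(cohort$maps, rs)
head(lat[, c("subject_id", "L", "R", "LQ", "dominance")], 3)
#>   subject_id         L        R         LQ dominance
#> 1      S0001 0.1248638 1.000821 -0.8752387       RLD
#> 2      S0002 0.2777443 1.001277 -0.7226100       RLD
#> 3      S0003 0.4337802 1.003278 -0.5676369       RLD

# a connectome with a planted negative QA-LQ block (segments 20-39),
# confounded by covariates, analyzed at the package defaults scaled down
g <- gen_local_connectome(200, 100, planted_effect(20, 20, -0.5, 0.3),
                          lq = lat$LQ[rep(1:12, length.out = 200)], seed = 1)
res <- run_connectometry(g$matrix, g$covariates, n_permutations = 500, seed = 2)
res
#> Connectometry result: 200 subjects, 100 segments
#>   variable: lq | T threshold: 3 | permutations: 500 | FDR: 0.01
#>   positively correlated tracks (significant, >= 20 mm): 0
#>   negatively correlated tracks (significant, >= 20 mm): 1 | lengths mm: 40
```

The recovered negative track covers the planted 20-segment block
(20 × 2 mm = 40 mm): higher anisotropy in that region goes with lower LQ,
i.e. with bilateral/right-shifted language representation — the direction
reported for commissural tracts. Shape metrics work the same way on files:

```r
b <- read_streamlines("bundle.tck")      # or .trk; world mm either way
compute_shape(b, voxel_size_mm = 2)
#>   mean_length_mm span_mm curl elongation diameter_mm volume_mm3 surface_area_mm2
```

A thin CLI wraps the same functions
(`Rscript inst/cli/latconn.R pipeline --out run1 --n 100 --seed 1`; see
`--help` for the `simulate`, `laterality`, `shape`, `connectometry` and
`groupstats` subcommands). Every run writes a JSON manifest (version,
configuration, seed, input hashes, no timestamps), so the same seed
reproduces every output byte for byte.

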