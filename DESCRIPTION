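Package: latconn
Title: Language Laterality, Correlational Connectometry and Tract Shape Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating white matter microstructure and tract geometry
    to hemispheric language dominance. Computes fMRI laterality quotients from
    grayordinate activation maps with per-ROI median thresholding and
    hemisphere-size normalization; runs correlational connectometry over
    subject-by-segment quantitative anisotropy matrices (covariate-adjusted
    Spearman partial correlation, contiguous track growing, permutation null
    of track length, FDR control); extracts bundle shape metrics (length,
    span, curl, elongation, diameter, volume, surface area) from streamline
    bundles; and provides group statistics (covariate-adjusted ANOVA, Tukey
    post hoc, Benjamini-Hochberg correction, linear regression). A seeded
    synthetic cohort generator with planted effects makes the full pipeline
    testable without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
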