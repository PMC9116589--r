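Package: sesbrain
Title: Genetic and Environmental Decomposition of Socioeconomic Gradients in Brain Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline separating genetic from environmental components
    of the association between socioeconomic status (SES) and regional gray
    matter volume (GMV). Provides factorial analysis of mixed data (FAMD) for
    summarizing mixed numeric/categorical SES indicators into principal
    components, mass-univariate voxel-based morphometry (VBM) with max-statistic
    permutation family-wise error control (Freedman-Lane scheme), genetic
    instrumental-variable (GIV) two-stage least squares correction of polygenic
    index measurement error, percent-attribution decomposition of association
    maps into polygenic and body-mass-index components, stacked block ridge
    regression for out-of-sample brain-to-SES prediction, and functional
    annotation of statistic maps against concept maps using spatial-
    autocorrelation-preserving surrogate permutations. A synthetic-data
    generator emulates the statistical structure of a population imaging cohort
    (latent genetic and environmental factors, split-sample polygenic indices
    at stated reliability, spatially autocorrelated voxel noise) so that every
    stage is testable without restricted data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    quadprog,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
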