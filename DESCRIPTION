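Package: thicknet
Title: Development of Structural Correlation Networks from Cortical Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds structural correlation (covariance) networks from
    participants-by-regions cortical morphometry tables and characterizes their
    development across adolescence. Networks are estimated by Pearson
    correlation of regional cortical thickness within overlapping age-defined
    participant windows, thresholded probabilistically by a bootstrap
    sign-consistency test with false-discovery-rate control, and summarized by
    global, nodal and community-level graph metrics. Developmental trajectories
    of these metrics are fitted with linear models and complexity-constrained
    REML smoothing splines, selected by AIC, and summarized by the maximum
    change and the age at the trajectory minimum with bootstrap confidence
    intervals. Community structure is obtained by multiresolution Louvain
    clustering with versatility-guided resolution selection and consensus
    partitioning. Associations between cortical maps are assessed with a
    spherical spin permutation test that preserves spatial contiguity and
    hemispheric symmetry. A synthetic-cohort generator with known ground truth
    (age-dependent block correlation structure, planted modules, regional
    thinning and myelination trends, spherical region layout) makes the whole
    pipeline testable without restricted study data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    mgcv,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
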