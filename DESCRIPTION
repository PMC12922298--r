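Package: isfcr
Title: Inter-Subject Functional Connectivity Analysis for Two-Group
    Naturalistic fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for inter-subject functional connectivity (ISFC) analysis
    of multi-subject region-of-interest BOLD time series acquired under a
    shared naturalistic stimulus. Implements post-fMRIPrep confound cleaning
    (discrete cosine high-pass regressors, linear detrending, joint nuisance
    regression, standardization) with framewise-displacement based subject
    exclusion; pairwise ISFC between all subject pairs with per-pair
    symmetrization and median group summaries; subject-wise permutation
    tests of group differences with signed significance masks and per-ROI
    count maps; and cross-dataset replication statistics (signed mask
    overlap, replication rate, ROI-shuffle permutation null, cross-matrix
    correlation). Includes a synthetic multi-subject BOLD generator with a
    shared latent stimulus, group-specific regional coupling, idiosyncratic
    noise, simulated motion confounds, and a closed-form expected-ISFC
    oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
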