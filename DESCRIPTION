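Package: sampenmap
Title: Voxelwise Sample Entropy Mapping and Group Statistics for 4D fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Computes sample entropy (SampEn) voxel by voxel on 4D BOLD fMRI
    time series, aggregates the resulting complexity maps over an integer
    label atlas into a scans-by-regions table, and runs the group-level
    statistical battery used in brain-entropy studies: Pearson correlation
    matrices across scans, paired t-tests with Bonferroni correction,
    balanced two-factor ANOVA with interaction, and test-retest reliability
    via the ICC(3,1) consistency coefficient. Includes a seeded synthetic
    cohort generator (AR(1) regularity with parcel, condition, subject and
    scan effects) with full ground truth for recovery testing, and a
    four-stage pipeline (simulate, map, aggregate, stats) with a
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
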