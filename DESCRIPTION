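Package: srnmap
Title: Transcriptomic-Neuroimaging Mapping of Receptor Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Projects brain-wide gene-expression maps of receptor genes onto
    parcellated fMRI time-series via two-stage multivariate ("dual")
    regression, yielding per-receptor network amplitude time-courses and
    functional connectivity maps. Provides permutation-based general linear
    model inference with one-dimensional threshold-free cluster enhancement,
    max-statistic family-wise error correction and exchangeability blocks;
    Spearman partial-correlation specificity analysis against co-expressed
    receptor families; and stepwise permutation canonical correlation
    analysis linking connectivity features to behavior in populations with
    family structure. Includes a synthetic-data generator emulating
    optogenetic-fMRI block designs, group and pharmacological effects, and
    populations with planted brain-behavior canonical modes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils, jsonlite, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
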