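Package: cmscore
Title: Cumulative Methylation Scoring for Cartridge-Based Liquid-Biopsy
    Methylation qPCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scoring and evaluation pipeline for circulating tumor DNA
    methylation measured by cartridge-based methylation-specific qPCR.
    Implements the four-step cumulative methylation (CM) algorithm
    (ACTB-referenced delta-Ct normalization, batch shift to positive
    values, censoring of signals beyond the 300-copy calibration median
    plus a fixed offset, and the 1200/delta-Ct gene methylation
    transform), calibration-table construction from spike-in replicates,
    replicate coefficient-of-variation quality control, diagnostic
    evaluation (Mann-Whitney group comparison, ROC with Youden threshold
    selection and DeLong confidence intervals, confusion metrics with
    Wilson intervals, Spearman concordance), longitudinal trajectory
    summaries, and a synthetic qPCR data generator that emulates spike-in
    replicate experiments, case/control cohorts, duplicate-user sets and
    serial on-treatment draws. File I/O uses plain CSV/JSON/YAML with
    fixed documented schemas, and a command-line interface chains the
    pipeline stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pROC,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
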