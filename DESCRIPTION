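Package: comepi
Title: Co-Occurrence and Mutual Exclusivity Analysis of DNA Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects co-occurrence (CO) and mutual-exclusivity (ME) patterns
    between gene promoter methylation states across tumor cohorts. Probe-level
    beta values are collapsed to promoter averages, dichotomized into a binary
    alteration matrix, and every gene pair is tested against a
    margin-calibrated independence background using exact Poisson-binomial
    tail probabilities. Significant events are filtered by tumor-versus-normal
    differential occurrence (Fisher's exact test) and cross-cancer recurrence,
    assembled into per-cancer and pan-cancer networks, mined for functional
    epigenetic modules of coordinated differential methylation and expression,
    and used to derive patient subtypes by consensus clustering with
    Kaplan-Meier / log-rank survival and clinical-feature association tests.
    Seeded synthetic-cohort generators with planted ground truth support
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    generics,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    igraph,
    survival,
    cluster,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pracma,
    withr
Config/testthat/edition: 3
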