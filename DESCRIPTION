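Package: trflpr
Title: Analysis of T-RFLP Community Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy toolkit for terminal restriction fragment length
    polymorphism (T-RFLP) community fingerprints: peak-table ingestion with
    relative-abundance filtering, cross-sample fragment binning and replicate
    averaging; evenness and turnover descriptors (Pareto-Lorenz PL20,
    moving-window rate of change from Pearson percent-change matrices);
    non-metric multidimensional scaling with Kruskal stress-1, a
    dimensionality-selection rule and a Monte Carlo stress randomization test;
    crossed permutational multivariate analysis of variance (PerMANOVA) with
    pairwise comparisons and a gamma asymptotic fallback; Dufrene-Legendre
    indicator value analysis with univariate permutation ANOVAs; in-silico
    restriction digestion of labeled amplicons (single and double digests,
    IUPAC-aware, both strands) with drift-tolerant matching of predicted to
    observed fragment sizes; and a synthetic study generator that emulates a
    seasonal two-treatment pot experiment for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
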