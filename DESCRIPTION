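Package: antshort
Title: Ant-Colony Short-Form Construction and Evaluation for Hierarchical Ordinal Scales
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds fixed-length short forms of hierarchical ordinal
    instruments (items nested in facets nested in domains) by MAX-MIN
    ant-system search over two-items-per-facet selections, and evaluates the
    result the way ordinal confirmatory factor analysis practice does:
    polychoric correlations with diagonally weighted least squares
    estimation, scaled chi-square fit statistics (CFI, RMSEA with confidence
    interval, SRMR), McDonald's omega reliability, a four-step ordinal
    measurement-invariance ladder, and criterion-validity statistics
    (Fisher-averaged correlations, confidence intervals for differences
    between dependent correlations, Cohen's d). Includes a probit
    graded-response generator for synthetic response data, data-quality
    screening (longstring, Mahalanobis distance, even-odd consistency), and
    the full selection pipeline: stratified train/test split, multi-run
    multi-algorithm search, consensus across runs, brute-force completion of
    unresolved facets, and Heywood-aware final ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
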