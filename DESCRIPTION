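Package: hotspotCNV
Title: Rare Copy-Number Variant Discovery and Cohort Association on Hotspot Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for rare copy-number variant (CNV)
    discovery from hotspot-targeted array-CGH intensities and for
    case-control association in small clinical cohorts. Simulates
    segmental-duplication hotspot arrays with configurable probe spacing and
    noise, converts per-probe log2 ratios to per-chromosome z-scores, decodes
    loss/neutral/gain segments with a three-state hidden Markov model,
    refines calls through a four-rule filter cascade (segment z-score, probe
    support, segmental-duplication overlap, length), classifies rarity
    against a control CNV database by 50 percent reciprocal overlap, runs a
    size-threshold burden test, and computes cohort carrier-rate statistics
    (chi-square, exact McNemar, Welch t). A replay mode reproduces the
    summary arithmetic of a published premutation-carrier cohort from its
    printed CNV table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    IRanges,
    optparse
Config/testthat/edition: 3
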