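Package: slipmsi
Title: Tumor-Only Microsatellite Instability Calling via a Multinomial
    Polymerase-Slippage Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies polymerase slippage at microsatellite loci from
    aligned sequencing reads with a multinomial model of per-repeat-unit
    deletion (hysteresis synthesis) and insertion (pre-synthesis), and
    calls microsatellite instability (MSI) from a single tumor sample
    against a panel-of-normals baseline. Includes a reference-genome
    microsatellite scanner, allele-length extraction from BAM/SAM with
    flank re-anchoring, closed-form slippage-rate estimators with
    Kolmogorov-Smirnov model-fitness testing, baseline construction with
    a coverage-based site filter, per-sample MSI scoring (percentage of
    unstable sites), rank-based AUC selection of discriminative sites,
    and a fully synthetic fixture generator with ground-truth
    annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    Rsamtools,
    GenomicRanges,
    IRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    pROC,
    withr
Config/testthat/edition: 3
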