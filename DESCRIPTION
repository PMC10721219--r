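Package: pulseDHS
Title: Dynamic and Static DNase Hypersensitive Site Analysis for
    Growth-Hormone Pulse-Regulated Chromatin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to discover and characterize growth-hormone
    pulse-driven ("dynamic") versus constitutively open ("static")
    DNase-I hypersensitive sites (DHS) in liver chromatin. Implements
    windowed differential accessibility testing between STAT5-high and
    STAT5-low samples with PCA-based outlier rejection, normalized
    DNase-I cut-site aggregate profiles with reads-in-peaks-per-million
    (RiPPM) scaling, DHS classification by sex bias and pulse response,
    TAD-constrained target-gene assignment, chromatin-state and motif
    annotation, hypophysectomy response classes for sex-biased genes,
    and a ratio-of-ratios enrichment score with Fisher exact testing
    and Benjamini-Hochberg adjustment. A synthetic-data module
    generates cut-site cohorts with the pulsatile/static structure the
    analysis assumes, so the full pipeline is testable without any
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    IRanges,
    S4Vectors,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
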