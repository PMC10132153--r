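Package: riboshift
Title: Classification of Transcriptional and Translational Regulation from
    Matched Proteomic and Polysome-Profiling Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classifies genes into a 27-group taxonomy of transcriptional
    versus translational regulation by combining per-feature direction calls
    on proteomic and total-mRNA abundance (two-tailed t tests with FDR
    control, ratio-of-means direction, and a confidence-interval containment
    equivalence rule) with monosome-to-polysome shift calls based on
    per-sample polysome/monosome ratios and the ratio-of-means X statistic.
    Includes ZOOPS expectation-maximization motif discovery over widths
    10-25 with exact PWM score p-values, localization of motif hits to
    5'UTR/CDS/3'UTR, upstream open reading frame detection under ATG-only
    and alternative-initiation-codon modes, and a synthetic multi-layer data
    generator with known ground-truth regulation groups, planted motifs, and
    planted uORFs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
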