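Package: chromfold
Title: Sub-Kilobase Chromatin Compaction from Fragment Lengths and
    Short-Range Contacts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies chromatin fiber compaction at the scale of a few
    nucleosomes from three complementary readouts. Processes radiation-induced
    correlated cleavage (RICC-seq) fragment length distributions through
    spike-in depth scaling, exponential length-bias correction, mononucleosome
    normalization, genomic-DNA background ratios, replicate confidence
    intervals and per-position Welch comparisons. Builds orientation-resolved
    short-range (< 1.5 kb) Micro-C contact probability curves, calls
    nucleosome-step contact peaks by negative second-derivative runs, and
    derives nucleosome repeat length and the odd/even (zig-zag) contact ratio.
    Orients Hi-C compartment scores against an active-mark reference track and
    classifies per-bin compartment shifts between conditions. A synthetic-data
    generator emulates correlated-cleavage fragment mixtures, MNase spike-in
    ladders, cis ligation pairs with nucleosome-comb distance structure, and
    paired compartment-score tracks, so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
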