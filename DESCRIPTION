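Package: rsde
Title: Region-Subtractive Differential Expression for Two-Color Spotted Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for region-subtractive differential-expression
    analysis of two-color spotted cDNA microarrays: GenePix-style intensity
    import, stringency filtering (flags, minimum intensity, median-ratio
    normalization factor), loess (MA) normalization, a fold-change threshold
    calibrated from self-self hybridizations, dye-swap reconciliation with a
    replicate-consensus caller, a from-scratch one-class Significance Analysis
    of Microarrays (SAM) with sign-flip permutation FDR, and the four-comparison
    subtractive logic that isolates genes exclusively dysregulated in a disease
    brain region. Includes a synthetic study generator with planted ground
    truth, and the companion validation-assay computations: GAPDH-normalized
    comparative-CT qRT-PCR with exact Mann-Whitney tests, ChIP-qPCR fold
    enrichment over input, and first-order cytochrome c oxidase rate constants
    normalized to citrate synthase activity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
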