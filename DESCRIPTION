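Package: isoenrich
Title: Allele Frequency Spectrum Comparison and Variant Enrichment in
    Bottlenecked Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing the folded allele frequency spectra of two
    population sequencing panels, as used to characterise founder-effect
    isolates against outbred reference populations. Implements minor allele
    frequency binning and cross-population sharing tables, delta-method
    enrichment ratios with confidence intervals and two-category tests,
    per-variant minor allele frequency fold-enrichment classification,
    noncentral chi-square association power and sample-size calculators, and
    a per-site Wright-Fisher forward simulator of a bottleneck-plus-growth
    demography with category-specific purifying selection for generating
    test data with the frequency-spectrum signatures the analyses expect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
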