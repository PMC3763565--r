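Package: arpeggio
Title: Spectral Compression and Deconvolution of ChIP-Seq Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compresses ChIP-seq experiments into deconvolved read-start
    autocorrelation profiles ("Arpeggio profiles") and their spectral
    densities. Computes DSP-style pair-count autocorrelation and
    opposing-strand cross-correlation of deduplicated 5' read starts,
    recovers the true immunoprecipitation signal by harmonic deconvolution
    against a spectrally matched control, estimates the full fragment-length
    distribution from single-end reads, quantifies nucleosome-spacing
    periodicity, and embeds collections of experiments by principal
    components of their spectral densities for clustering and
    classification. Includes a seeded simulator of stranded single-end
    reads with known ground truth for isolated factors, phased nucleosome
    arrays, polymerase-like spread signals and accessibility-biased
    background controls.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    methods,
    stats,
    tools,
    utils,
    jsonlite,
    data.table,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Rsamtools,
    GenomicAlignments,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
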