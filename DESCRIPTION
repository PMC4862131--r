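Package: clonemut
Title: Mutation Calling and Mutational Spectrum Analysis for Isogenic Clone
    Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for whole-genome mutagenesis assays based on sequencing
    multiple isogenic cell clones. Implements a unique-mutation caller that
    identifies single-nucleotide variants and short indels private to exactly
    one clone of a cohort using allele-frequency, coverage and
    cross-sample reference filters; 96-channel trinucleotide mutation
    spectra with genome triplet-frequency normalisation and cross-species
    adjustment; dinucleotide-mutation detection and indel sequence-context
    classification with strand folding; transcription-related mutation
    density and strand-bias statistics; a probability model for
    mutation-driven genetic reversion; and a synthetic cohort generator
    that emulates multi-clone pileups for validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    graphics,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
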