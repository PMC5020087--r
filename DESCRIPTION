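Package: ssrforge
Title: Genome-Scale Microsatellite Mining, Marker Design and In Silico PCR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines simple sequence repeats (SSRs, microsatellites) from DNA
    sequences of arbitrary length using an overlap-chunking strategy with
    coordinate lift-back, computes five statistical classifications of the
    discovered loci with publication-ready plots, designs deduplicated
    PCR markers from SSR flanking sequences, screens marker polymorphism
    and transferability by electronic PCR, and exports loci and markers as
    GFF3 tracks for genome browsers. A synthetic-genome generator with
    planted repeat loci and mutated allele variants supports fully
    self-contained testing.
License: MIT
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    rtracklayer,
    seqinr,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
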