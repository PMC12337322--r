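Package: duplexCpG
Title: Duplex CpG-State Calling from Hairpin-Linked Methylation Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates and decodes hairpin-linked, deamination-based
    sequencing libraries that read out the full double-stranded
    modification state of CpG dyads. Each CpG site carries one of nine
    states built from C, 5-methylcytosine (mC) and
    5-hydroxymethylcytosine (hmC) on the two strands; four binary
    methylation calls per site (original and copy strand of each original
    strand) encode the state. The package provides a forward simulator of
    the library chemistry (hairpin adapter ligation, copy-strand
    synthesis with maintenance copy-methylation opposite mC only,
    enzymatic deamination, PCR duplication, sequencing error), the
    decoding pipeline (adapter-configuration filtering, four-insert
    extraction, three-letter converted-space alignment, deduplication,
    per-site state compilation), spike-in based confusion-matrix
    evaluation, linear deconvolution correction of genome-wide state
    fractions, and per-site/region/profile summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
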