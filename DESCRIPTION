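Package: orphanscan
Title: Motif-Demarcated Toxin/Immunity Module Annotation and Locus Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates bacterial contact-dependent growth inhibition (CDI) and
    rearrangement-hotspot (Rhs) loci for polymorphic toxin/immunity modules.
    Scans nucleotide loci in all six reading frames for the peptide motifs that
    demarcate variable toxin C-terminal domains (VENN in CdiA, PxxxxDPxGL in
    Rhs), enumerates open reading frames with start-codon and Shine-Dalgarno
    assessment, assembles motif hits and small immunity ORFs into ordered,
    positionally labelled main and orphan modules, and compares two annotated
    loci with anchored identity blocks to call divergence breakpoints at motif
    junctions, deletion-fusion events and module interchange. Includes a
    ground-truthed synthetic locus generator for validation and the
    efficiency-corrected qPCR relative-expression calculation used for module
    transcription measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
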