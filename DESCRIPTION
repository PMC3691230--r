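Package: scaffoldsmith
Title: Scaffold Assembly, Annotation Lift-Over and GenBank Submission Files
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for finishing microbial draft genomes from a human-editable
    scaffold plan. A plain-text YAML scaffold file describing contig order,
    orientation, trims, patch inserts and unresolved gaps is rendered into the
    draft genome sequence; GFF3 gene annotations in contig coordinates are
    lifted onto scaffold coordinates with an auditable drop report; and the
    file set required for GenBank submission (assembled FASTA, contig
    component FASTA, AGP 2.0, NCBI 5-column feature table) is generated
    deterministically, so the whole finishing process can be scripted and
    version-controlled.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    yaml,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    BiocGenerics,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
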