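Package: mitoasym
Title: Mitogenome Annotation Arithmetic, Strand Asymmetry and Heteroplasmy Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing annotated circular mitochondrial genomes:
    derived annotation statistics (gene and protein lengths, signed intergenic
    gaps, start/stop codon classes), strand compositional asymmetry (GC and AT
    skew, codon-position GC content), codon and amino-acid usage with
    correspondence analysis, and a filter-cascade heteroplasmy caller operating
    on samtools-mpileup text with codon-level effect annotation under the
    vertebrate mitochondrial genetic code. A synthetic mitogenome and read
    simulator with known ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    seqinr,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
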