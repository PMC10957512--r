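Package: vdjannot
Title: Directed Annotation of Immunoglobulin and T Cell Receptor V, D and J Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finds and annotates immunoglobulin (IG) and T cell receptor (TR)
    V, D and J germline genes in genomic assemblies by directed search against
    a reference set of known alleles. Candidate genes located by nucleotide
    similarity are refined by position-weight-matrix detection of their
    regulatory flanking features (recombination signal sequence heptamers and
    nonamers, leader exons L-PART1 and L-PART2, J-motif and splice sites) and
    classified as Functional, ORF or pseudogene following IMGT-style criteria.
    Includes a synthetic-locus simulator with ground truth for validation, a
    PWM builder, and CSV/GFF3 report writers.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    data.table,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
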