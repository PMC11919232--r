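Package: asotriage
Title: Amenability Triage of Loss-of-Function Variants for Splice-Switching Antisense Oligonucleotides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic, auditable rule engine for deciding whether a
    (likely) pathogenic loss-of-function variant is amenable to a
    splice-switching antisense-oligonucleotide (ssASO) strategy, either
    cryptic-splice-site blocking or single-exon skipping. Builds a full
    transcript/reading-frame model with exact HGVS-c coordinate arithmetic
    (including intronic offsets), annotates variants against splice-site,
    splice-region, branch-point and deep-intronic windows, simulates
    exon skipping with junction-codon reconstruction, scores pathogenic
    missense hotspots, and runs clinical decision trees that emit a verdict
    together with the ordered trace of every rule fired. Ships a synthetic
    fixture generator reproducing an eight-archetype hypothetical transcript
    and a command-line interface for end-to-end triage from standard file
    formats (gene-model JSON, GFF3+FASTA, VCF, BED, TSV).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    utils,
    Biostrings,
    BiocGenerics,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
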