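Package: resistseq
Title: Identify Resistance Mutations from Whole-Genome Resequencing of
    Bacterial Mutants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, fully simulatable re-implementation of the
    resequencing strategy used to locate the genetic target of a two-peptide
    bacteriocin: resistant-mutant reads are compared against a crude draft
    assembly of the sensitive wild-type genome, raw sequence differences are
    cleaned by a defined false-positive exclusion and verification scheme
    (wild-type self-comparison, assembly-coverage flags, depth/allele-fraction/
    strand checks), surviving mutations are annotated at codon level
    (silent, missense, nonsense, frameshift with truncation lengths),
    localized against a hydropathy-predicted transmembrane topology, and
    related to broth-microdilution MIC fold-resistance. A synthetic-data
    module generates truth-tracked genomes, mutant strains, paired-end read
    sets, crude-assembly emulations, difference-report fixtures and
    dose-response plates so every stage is testable against known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    data.table,
    GenomicRanges,
    IRanges,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
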