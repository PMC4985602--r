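# The 58-record difference-report fixture reproducing the study's
# filtering structure: 11 wild-type-shared differences in unreliable
# low-coverage assembly regions, 11 more shared by several mutants in such
# regions, and the 36 retained records with their printed contig labels,
# positions, assembly coverages, strain-presence pattern and annotations.
# Verification metrics (site depth, strand split, allele fraction) are not
# printed per record in the source table; they are synthesized
# deterministically inside the ranges the study reports (depth 154-484,
# balanced strands, fraction 0.90-1.00).

MUTANT_STRAINS <- c("JK1", "JK2", "JK3", "JK4", "JK5", "JK6", "JK8",
                    "JK9", "JK10", "JK11")
ALL_STRAINS <- c("VT1", MUTANT_STRAINS)

# The 36 retained rows: contig | printed position | assembly coverage
# (NA = not printed) | annotation | strains | executable type/ref/alt
# (ref/alt synthesized for rows whose alleles are not printed; the focal
# contig-10 rows match the engineered focal gene exactly, with the
# codon-177 insertion left-normalized to position 2737).
retained_fixture_rows <- function() {
  rows <- list(
    list("Contig 3", 15305, 5, "Silent mutation in D-Ala-D-Ala carboxypeptidase", "JK8", "substitution", 15305, "T", "C"),
    list("Contig 7", 17428, 16, "ACG-ATG = 40T-M in S4 RNA-binding domain protein", "JK4,JK5", "substitution", 17428, "C", "T"),
    list("Contig 10", 2518, 44, "CGA-TGA = 104R-stop in APC family amino acid-polyamine-organocation transporter, 610 aa", "JK3", "substitution", 2518, "C", "T"),
    list("Contig 10", 2739, 30, "TTC-TTTC = 177F-frameshift in APC family amino acid-polyamine-organocation transporter", "JK4,JK5,JK6", "insertion", 2737, "T", "TT"),
    list("Contig 10", 3337, 18, "GCG-ACG = 377A-T in APC family amino acid-polyamine-organocation transporter", "JK2", "substitution", 3337, "G", "A"),
    list("Contig 10", 3367, 19, "TCT-CCT = 387S-P in APC family amino acid-polyamine-organocation transporter", "JK1", "substitution", 3367, "T", "C"),
    list("Contig 10", 3393, 23, "TGG-TGA = 395W-stop in APC family amino acid-polyamine-organocation transporter", "JK10", "substitution", 3393, "G", "A"),
    list("Contig 10", 3482, 21, "ATG-AAG = 425M-K in APC family amino acid-polyamine-organocation transporter", "JK11", "substitution", 3482, "T", "A"),
    list("Contig 10", 3491, 22, "CAT-CGT = 428H-R in APC family amino acid-polyamine-organocation transporter", "JK8,JK9", "substitution", 3491, "A", "G"),
    list("Contig 10", 12129, 6, "GGT-AGT = G-S in nucleic acid-binding protein", "JK9", "substitution", 12129, "G", "A"),
    list("Contig 11", 2629, 6, "GTA-ATA = V-I in predicted metal-dependent hydrolase", "JK5", "substitution", 2629, "G", "A"),
    list("Contig 12", 3366, 15, "GTG-GCG = V-A in Met-tRNA formyl transferase", "JK2", "substitution", 3366, "T", "C"),
    list("Contig 15", 5486, 18, "Intergenic region according to Glimmer, no BlastX hits", "JK10", "substitution", 5486, "A", "G"),
    list("Contig 17", 10149, 45, "Just downstream of Glimmer orf 10 branched chain amino acid aminotransferase", "JK1", "substitution", 10149, "C", "T"),
    list("Contig 23", 2907, 10, "ATT-GTT = I-V in UTP-glucose-1-P uridylyltransferase", "JK4", "substitution", 2907, "A", "G"),
    list("Contig 23", 13717, 32, "GTG-GGTG = frameshift in glutamine ABC transporter, permease/substrate-binding protein", "JK8,JK9", "insertion", 13717, "G", "GG"),
    list("Contig 26", 9532, 60, "ATT-GTT = I-V in purH, bifunctional phosphoribosylaminoimidazolecarboxamide formyltransferase/IMP cyclohydrolase", "JK8,JK9", "substitution", 9532, "A", "G"),
    list("Contig 28", 11172, 14, "GGA-GGGA = frameshift 55 aa from end of integral membrane protein", "JK1", "insertion", 11172, "G", "GG"),
    list("Contig 36", 7084, 57, "GCT-GTT = A-V in oxoacyl-ACP synthase", "JK2", "substitution", 7084, "C", "T"),
    list("Contig 37", 167, NA, "GAA-GAG = E-E silent mutation in aspartate kinase", "JK2", "substitution", 167, "A", "G"),
    list("Contig 42", 4874, 6, "CTA-CCA = L-P in putative dienelactone hydrolase (no gene predicted by Glimmer)", "JK4,JK5,JK6", "substitution", 4874, "T", "C"),
    list("Contig 47", 2473, 7, "Deletion of T in Intergenic region according to Glimmer", "", "deletion", 2473, "AT", "A"),
    list("Contig 64", 3734, 4, "AGT-AGC = silent mutation in nucleotide-binding protein", "JK4", "substitution", 3734, "T", "C"),
    list("Contig 69", 1283, 14, "GGT-AGT = G-S in gene with similarity to HTH AraC regulatory protein", "JK1", "substitution", 1283, "G", "A"),
    list("Contig 73", 2467, 19, "Frameshift after amino acid 187 in PTS system mannose family transporter subunit IID protein.", "JK1", "insertion", 2467, "A", "AA"),
    list("Contig 77", 233, 28, "CAC-CAT = Silent mutation in pyruvate carboxylase", "JK4,JK5,JK6", "substitution", 233, "C", "T"),
    list("Contig 79", 2182, 15, "GAC-AAC = D-N in putative uncharacterized protein. Verified to be a mutation", "JK1", "substitution", 2182, "G", "A"),
    list("Contig 84", 4263, 8, "BLAST and Glimmer: not coding region, downstream of GTP-binding protein TypA gene", "JK11", "substitution", 4263, "G", "A"),
    list("Contig 85", 8117, 5, "AAA-AAAA = frameshift toward end of Glimmer prediction, no Blast similarity to anything", "JK11", "insertion", 8117, "A", "AA"),
    list("Contig 103", 928, 81, "ATT-ATC = silent mutation in glutathione reductase", "JK10", "substitution", 928, "T", "C"),
    list("Contig 111", 1948, 30, "AAT-AAC = silent mutation in oxidoreductase", "JK5", "substitution", 1948, "T", "C"),
    list("Contig 114", 6645, 2, "GGA-GAA = G-E in MccC family protein - putative peptidase", "JK6", "substitution", 6645, "G", "A"),
    list("Contig 132", 1556, 6, "Intergenic region", "JK11", "substitution", 1556, "C", "A"),
    list("Contig 146", 971, 23, "CAG-CGG = Q-R in acetylornithine deacetylase", "JK5", "substitution", 971, "A", "G"),
    list("Contig 153", 1131, 2, "6 nt downstream of penicillin-binding protein/beta-lactamase", "JK2", "substitution", 1131, "G", "T"),
    list("Contig 160", 2010, 5, "6 nt downstream of conserved hypothetical protein, putative receptor", "JK10", "substitution", 2010, "T", "A"))
  do.call(rbind, lapply(rows, function(r) {
    data.frame(contig = r[[1]], printed_position = as.integer(r[[2]]),
               assembly_coverage = as.numeric(r[[3]]), annotation = r[[4]],
               strains = r[[5]], type = r[[6]],
               position = as.integer(r[[7]]), ref_allele = r[[8]],
               alt_allele = r[[9]], stringsAsFactors = FALSE)
  }))
}

presence_matrix <- function(strain_strings) {
  lists <- strsplit(strain_strings, ",", fixed = TRUE)
  m <- vapply(ALL_STRAINS, function(s)
    vapply(lists, function(x) s %in% x, logical(1)),
    logical(length(strain_strings)))
  colnames(m) <- paste0("present_", ALL_STRAINS)
  m
}

#' Build the 58-record difference-report fixture
#'
#' Reconstructs the study's raw difference report: 36 retained records with
#' their printed contig/position/coverage/annotation/strain-presence
#' values, plus 22 excluded records (11 shared with the wild type, 11
#' shared among several mutants) placed in the unreliable 1-5x
#' assembly-coverage band. Positions and alleles of the excluded records
#' and all per-record verification metrics are synthesized
#' deterministically; only their counts and flag structure follow the
#' study. The `position` column is the executable (left-normalized)
#' coordinate; `printed_position` preserves the report's value, which for
#' the codon-177 insertion is the first read/reference disagreement (2739)
#' rather than the left-normalized anchor (2737).
#'
#' @return A [difference_records()] table with 58 rows, presence columns
#'   for VT1 and the ten mutants, synthesized verification metrics, and a
#'   `printed_position` column.
#' @examples
#' fx <- make_difference_fixture()
#' nrow(fx)                      # 58
#' sum(fx$present_VT1)           # 11
#' @export
make_difference_fixture <- function() {
  ret <- retained_fixture_rows()
  n <- nrow(ret)
  local_seed(58L, {
    # verification metrics inside the verified ranges; strand split is an
    # even split so balance is exact
    depth <- round(seq(154, 484, length.out = n))[sample.int(n)]
    frac <- round(stats::runif(n, 0.92, 1.0), 3)
    ret$depth <- depth
    ret$alt_fwd <- ceiling(round(depth * frac) / 2)
    ret$alt_rev <- round(depth * frac) - ret$alt_fwd
    ret$alt_fraction <- frac
    ret <- cbind(ret, presence_matrix(ret$strains))

    # 11 differences also present in the wild type (assembly errors)
    wt_contigs <- paste0("Contig ", c(2, 5, 9, 19, 31, 44, 58, 71, 90,
                                      118, 140))
    wt_pos <- sample.int(20000L, 11L)
    wt_strains <- vapply(seq_len(11L), function(i) {
      n_mut <- sample(3:10, 1L)
      paste(c("VT1", sample(MUTANT_STRAINS, n_mut)), collapse = ",")
    }, character(1))
    wt <- data.frame(contig = wt_contigs, printed_position = wt_pos,
                     assembly_coverage = sample.int(5L, 11L, replace = TRUE),
                     annotation = "Low-coverage region, shared with wild type",
                     strains = wt_strains, type = "substitution",
                     position = wt_pos,
                     ref_allele = sample(DNA_BASES, 11L, replace = TRUE),
                     stringsAsFactors = FALSE)
    wt$alt_allele <- vapply(wt$ref_allele, function(b)
      sample(setdiff(DNA_BASES, b), 1L), character(1))
    wt$depth <- sample(30:90, 11L, replace = TRUE)
    wt$alt_fwd <- ceiling(wt$depth * 0.48)
    wt$alt_rev <- floor(wt$depth * 0.48)
    wt$alt_fraction <- 0.96
    wt <- cbind(wt, presence_matrix(wt$strains))

    # 11 differences shared by several mutants in low-coverage regions
    lc_contigs <- paste0("Contig ", c(6, 14, 21, 33, 41, 52, 66, 88, 101,
                                      125, 150))
    lc_pos <- sample.int(20000L, 11L)
    lc_strains <- vapply(seq_len(11L), function(i) {
      n_mut <- sample(2:6, 1L)
      paste(sample(MUTANT_STRAINS, n_mut), collapse = ",")
    }, character(1))
    lc <- data.frame(contig = lc_contigs, printed_position = lc_pos,
                     assembly_coverage = sample.int(5L, 11L, replace = TRUE),
                     annotation = "Low-coverage region, shared among mutants",
                     strains = lc_strains, type = "substitution",
                     position = lc_pos,
                     ref_allele = sample(DNA_BASES, 11L, replace = TRUE),
                     stringsAsFactors = FALSE)
    lc$alt_allele <- vapply(lc$ref_allele, function(b)
      sample(setdiff(DNA_BASES, b), 1L), character(1))
    lc$depth <- sample(30:90, 11L, replace = TRUE)
    lc$alt_fwd <- ceiling(lc$depth * 0.48)
    lc$alt_rev <- floor(lc$depth * 0.48)
    lc$alt_fraction <- 0.95
    lc <- cbind(lc, presence_matrix(lc$strains))

    out <- rbind(ret, wt, lc)
    out$strains <- NULL
    rownames(out) <- NULL
    difference_records(out)
  })
}

#' Synthetic stand-in for the study's focal contig
#'
#' A deterministic 13-kb "Contig 10" carrying the engineered focal gene at
#' positions 2209-4041, so fixture replay can regenerate codon-level
#' annotations from sequence. The flanking sequence is synthetic; only the
#' gene region is meaningful.
#'
#' @return Named character vector with one element, `"Contig 10"`.
#' @export
fixture_contigs <- function() {
  local_seed(1010L, {
    s <- random_dna(13000L)
    s <- str_overwrite(s, FOCAL_GENE_START, focal_gene_seq())
    s <- str_overwrite(s, FOCAL_GENE_START - 3L, "TAA")
    c("Contig 10" = s)
  })
}

#' Gene models used for fixture replay
#'
#' @return The focal gene model on "Contig 10".
#' @export
fixture_gene_models <- function() {
  g <- focal_gene_model("Contig 10")
  g$focal <- TRUE
  g
}
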