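# Codon arithmetic, ORF discovery, consequence classification and
# truncation lengths, cross-checked against whole-protein translation.

test_that("coordinate-to-codon arithmetic matches the published table", {
  g <- gene_model("Contig 10", 2209, 4041, "+", "apc")
  pos <- c(2518L, 2739L, 3337L, 3367L, 3393L, 3482L, 3491L)
  expect_identical(map_position_to_codon(g, pos),
                   c(104L, 177L, 377L, 387L, 395L, 425L, 428L))
  expect_identical(protein_length(g), 610L)
  expect_identical(map_position_to_codon(g, g$start), 1L)
  expect_error(map_position_to_codon(g, 2208L), "intergenic")
  expect_identical(protein_length(gene_model("c", 1, 6)), 1L)
})

test_that("codon mapping round-trips on both strands", {
  fwd <- gene_model("c", 101L, 160L, "+")
  rev <- gene_model("c", 101L, 160L, "-")
  for (codon in c(1L, 7L, 20L)) {
    fpos <- fwd$start + 3L * (codon - 1L) + 0:2
    expect_true(all(map_position_to_codon(fwd, fpos) == codon))
    rpos <- rev$end - 3L * (codon - 1L) - 0:2
    expect_true(all(map_position_to_codon(rev, rpos) == codon))
  }
})

test_that("ORF discovery recovers designed genes on both strands", {
  g <- build_genome(seed = 3L)
  focal <- g$genes[g$genes$focal, ]
  orfs <- find_orfs(g$contigs[focal$contig], min_length = 300L)
  hit <- orfs[orfs$start == focal$start & orfs$end == focal$end &
                orfs$strand == "+", ]
  expect_identical(nrow(hit), 1L)
  expect_identical(nchar(hit$protein), 610L)
  # a designed reverse-strand gene is recovered with the correct protein
  minus <- g$genes[g$genes$strand == "-", ][1, ]
  orfs2 <- find_orfs(g$contigs[minus$contig], min_length = 300L)
  hit2 <- orfs2[orfs2$start == minus$start & orfs2$end == minus$end, ]
  expect_identical(hit2$strand, "-")
  expect_identical(hit2$protein,
                   resistseq:::translate_to_stop(
                     resistseq:::gene_cds(minus, g$contigs))$protein)
  # a contig of stop codons yields nothing
  expect_identical(nrow(find_orfs(c(x = strrep("TAA", 200L)),
                                  min_length = 90L)), 0L)
})

test_that("substitutions classify as silent, missense or nonsense", {
  contigs <- fixture_contigs()
  genes <- fixture_gene_models()
  sub_rec <- function(pos, ref, alt) {
    data.frame(contig = "Contig 10", position = pos, ref_allele = ref,
               alt_allele = alt, type = "substitution")
  }
  non <- classify(sub_rec(2518L, "C", "T"), genes, contigs)
  expect_identical(non$class, "nonsense")
  expect_identical(non$codon_index, 104L)
  expect_identical(non$truncation_after, 103L)
  expect_match(non$annotation, "^CGA-TGA = 104R-stop")
  mis <- classify(sub_rec(3482L, "T", "A"), genes, contigs)
  expect_identical(mis$class, "missense")
  expect_match(mis$annotation, "^ATG-AAG = 425M-K")
  # a synonymous third-base change is silent: codon 104 CGA -> CGG (both R)
  sil <- classify(sub_rec(2520L, "A", "G"), genes, contigs)
  expect_identical(sil$class, "silent")
  expect_identical(sil$ref_residue, sil$alt_residue)
  # outside every gene
  int <- classify(sub_rec(12129L, "G", "A"), genes, contigs)
  expect_identical(int$class, "intergenic")
  down <- classify(sub_rec(4047L, "A", "G"), genes, contigs)
  expect_identical(down$class, "downstream_proximal")
  expect_match(down$annotation, "^6 nt downstream")
})

test_that("records overlapping two genes annotate against both", {
  contigs <- fixture_contigs()
  genes <- rbind(fixture_gene_models(),
                 cbind(gene_model("Contig 10", 3490L, 4053L, "+",
                                  "overlapper"), focal = FALSE))
  call <- classify(data.frame(contig = "Contig 10", position = 3491L,
                              ref_allele = "A", alt_allele = "G",
                              type = "substitution"), genes, contigs)
  expect_identical(nrow(call), 2L)
  expect_true(all(call$ambiguous))
  expect_setequal(call$gene, c(fixture_gene_models()$name, "overlapper"))
})

test_that("frameshifts report the engineered truncation lengths", {
  contigs <- fixture_contigs()
  genes <- fixture_gene_models()
  ins <- data.frame(contig = "Contig 10", position = 2737L,
                    ref_allele = "T", alt_allele = "TT",
                    type = "insertion")
  call <- classify(ins, genes, contigs)
  expect_identical(call$class, "frameshift")
  expect_identical(call$codon_index, 177L)
  expect_identical(call$truncation_after, 190L)
  expect_match(call$annotation, "^TTC-TTTC = 177F-frameshift")
  fs <- frameshift_effect(genes[1, ], contigs, ins)
  expect_identical(fs$truncation_after, 190L)
  expect_identical(fs$tail_length, 14L)
  expect_false(fs$in_frame_restored)
  # an insertion followed by a compensating deletion before any shifted
  # stop restores the frame
  del <- data.frame(contig = "Contig 10", position = 2745L,
                    ref_allele = substr(contigs[[1]], 2745L, 2746L),
                    alt_allele = substr(contigs[[1]], 2745L, 2745L),
                    type = "deletion")
  fs2 <- frameshift_effect(genes[1, ], contigs, rbind(ins, del))
  expect_true(fs2$in_frame_restored)
  expect_true(is.na(fs2$truncation_after))
})

test_that("classification agrees with whole-protein translation diffs", {
  g <- build_genome(seed = 4L)
  focal_contig <- g$genes$contig[g$genes$focal][1]
  gene <- g$genes[g$genes$focal, ]
  specs <- resistseq:::focal_mutation_specs(focal_contig)
  inj <- inject_mutations(g, specs)
  ref_prot <- resistseq:::translate_to_stop(
    resistseq:::gene_cds(gene, g$contigs))$protein
  for (i in seq_len(nrow(inj$manifest))) {
    m <- inj$manifest[i, ]
    call <- classify(m, g$genes, g$contigs)
    mut_contigs <- inj$genomes[[m$strain]]
    mut_prot <- resistseq:::translate_to_stop(
      substr(mut_contigs[[gene$contig]], gene$start,
             nchar(mut_contigs[[gene$contig]])))$protein
    if (call$class %in% c("nonsense", "frameshift")) {
      expect_identical(nchar(mut_prot),
                       as.integer(call$truncation_after))
    } else if (call$class == "missense") {
      d <- which(charToRaw(mut_prot) != charToRaw(ref_prot))
      expect_identical(d, as.integer(call$codon_index))
      expect_identical(substr(mut_prot, d, d), call$alt_residue)
    }
  }
})
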