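# Generator properties: determinism, focal-gene engineering, mutation
# injection, read simulation, crude-assembly emulation, dose-response.

test_that("genome generation is deterministic and well-formed", {
  g1 <- build_genome(seed = 11L)
  g2 <- build_genome(seed = 11L)
  expect_identical(g1$contigs, g2$contigs)
  expect_identical(g1$genes, g2$genes)
  # gene invariants: inside contigs, multiple of 3, no internal stop
  for (i in seq_len(nrow(g1$genes))) {
    gene <- g1$genes[i, ]
    expect_lte(gene$end, nchar(g1$contigs[[gene$contig]]))
    expect_identical((gene$end - gene$start + 1L) %% 3L, 0L)
    cds <- resistseq:::gene_cds(gene, g1$contigs)
    tr <- resistseq:::translate_to_stop(cds)
    expect_true(tr$hit_stop)
    expect_identical(tr$n_residues, protein_length(gene))
  }
  # repeat copies at >= 95% identity to their source
  for (i in seq_len(nrow(g1$repeats))) {
    r <- g1$repeats[i, ]
    a <- substr(g1$contigs[[r$contig]], r$start, r$end)
    b <- substr(g1$contigs[[r$src_contig]], r$src_start, r$src_end)
    ident <- 1 - resistseq:::count_mismatches(a, b) / nchar(a)
    expect_gte(ident, 0.95)
  }
})

test_that("the focal gene spans 1,833 nt and encodes 610 residues", {
  g <- build_genome(seed = 3L)
  focal <- g$genes[g$genes$focal, ]
  expect_identical(focal$end - focal$start + 1L, 1833L)
  expect_identical(protein_length(focal), 610L)
  cds <- resistseq:::gene_cds(focal, g$contigs)
  tr <- resistseq:::translate_to_stop(cds)
  expect_identical(tr$n_residues, 610L)
})

test_that("single-contig genomes without repeats have no repeat intervals", {
  g <- build_genome(n_contigs = 1L, total_length = 12000L,
                    gene_density = 0.3, repeat_spec = NULL, seed = 2L)
  expect_identical(nrow(g$repeats), 0L)
})

test_that("infeasible gene density is rejected with the conflict stated", {
  expect_error(build_genome(total_length = 30000L, gene_density = 3,
                            repeat_spec = NULL, seed = 1L),
               "gene_density")
})

test_that("mutation injection matches specs exactly and validates refs", {
  g <- tiny_genome()
  cn <- names(g$contigs)[1]
  ref <- substr(g$contigs[[cn]], 5000, 5000)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  specs <- data.frame(contig = cn, position = 5000L, ref_allele = ref,
                      alt_allele = alt, strains = "S1")
  inj <- inject_mutations(g, specs)
  mut <- inj$genomes$S1[[cn]]
  wt <- g$contigs[[cn]]
  diff_at <- which(charToRaw(mut) != charToRaw(wt))
  expect_identical(diff_at, 5000L)
  # empty spec list leaves the strain set empty; ref mismatch aborts
  expect_identical(nrow(inject_mutations(g, specs[0, ])$manifest), 0L)
  bad <- specs
  bad$ref_allele <- alt
  expect_error(inject_mutations(g, bad), "mismatch")
})

test_that("focal nonsense and frameshift mutations truncate as engineered", {
  g <- build_genome(seed = 4L)
  specs <- resistseq:::focal_mutation_specs(
    g$genes$contig[g$genes$focal][1])
  inj <- inject_mutations(g, specs)
  gene <- g$genes[g$genes$focal, ]
  product_len <- function(strain) {
    cs <- inj$genomes[[strain]][[gene$contig]]
    resistseq:::translate_to_stop(
      substr(cs, gene$start, nchar(cs)))$n_residues
  }
  expect_identical(product_len("JK3"), 103L)   # nonsense at codon 104
  expect_identical(product_len("JK4"), 190L)   # frameshift at codon 177
  expect_identical(product_len("JK10"), 394L)  # nonsense at codon 395
  # frameshift shifts the downstream frame by +1
  jk4 <- inj$genomes$JK4[[gene$contig]]
  expect_identical(nchar(jk4), nchar(g$contigs[[gene$contig]]) + 1L)
})

test_that("error-free reads are exact substrings and coverage is on target", {
  g <- tiny_genome()
  p <- read_sim_params(mean_coverage = 30, error_rate = 0, seed = 9L)
  rs <- simulate_reads(g$contigs, p)
  reads <- c(rs$r1, rs$r2)
  joined <- paste(unlist(g$contigs), collapse = "#")
  joined_rc <- paste(revcomp(unlist(g$contigs)), collapse = "#")
  hits <- vapply(reads[seq_len(200)], function(r)
    grepl(r, joined, fixed = TRUE) || grepl(r, joined_rc, fixed = TRUE),
    logical(1))
  expect_true(all(hits))
  realized <- sum(nchar(reads)) / sum(nchar(g$contigs))
  expect_lt(abs(realized - 30) / 30, 0.1)
  # determinism and seed sensitivity
  expect_identical(simulate_reads(g$contigs, p)$r1, rs$r1)
  p2 <- p; p2$seed <- 10L
  expect_false(identical(simulate_reads(g$contigs, p2)$r1, rs$r1))
})

test_that("strand sampling at deep sites stays within binomial bounds", {
  g <- tiny_genome()
  rs <- simulate_reads(g$contigs, read_sim_params(mean_coverage = 50,
                                                  error_rate = 0,
                                                  seed = 21L))
  idx <- build_index(g$contigs)
  aln <- map_reads(c(rs$r1, rs$r2), idx, g$contigs)
  pile <- build_pileup(aln, g$contigs)
  # interior positions only: end-proximal windows are strand-one-sided by
  # construction of fully-contained paired fragments
  cols <- pileup_columns(pile, data.frame(contig = names(g$contigs)[1],
                                          pos = seq(1000L, 5000L, 250L)))
  for (i in seq_len(nrow(cols))) {
    n <- cols$fwd[i] + cols$rev[i]
    ci <- stats::binom.test(cols$fwd[i], n, 0.5,
                            conf.level = 0.99)$p.value
    expect_gt(ci, 0.01 / nrow(cols))  # Bonferroni-style guard
  }
})

test_that("crude-assembly errors are confined to the unreliable band", {
  g <- build_genome(seed = 6L)
  asm <- emulate_crude_assembly(g, assembly_params(seed = 6L))
  expect_gt(nrow(asm$errors), 0L)
  for (i in seq_len(nrow(asm$errors))) {
    e <- asm$errors[i, ]
    expect_lte(asm$coverage[[e$contig]][e$position], 5L)
    expect_identical(substr(g$contigs[[e$contig]], e$position, e$position),
                     e$truth_base)
    expect_identical(substr(asm$contigs[[e$contig]], e$position,
                            e$position), e$assembly_base)
  }
  # zero low-coverage fraction and no repeats -> contigs untouched
  g0 <- build_genome(seed = 6L, repeat_spec = NULL)
  asm0 <- emulate_crude_assembly(
    g0, assembly_params(low_coverage_fraction = 0, seed = 6L))
  expect_identical(asm0$contigs, g0$contigs)
})

test_that("dose-response generator crosses 50% inhibition at the true MIC", {
  s <- make_dose_response(0.5, 12L, top_concentration = 8,
                          noise_sd = 0, seed = 1L)
  m <- estimate_mic(s)
  expect_identical(m$censored, "none")
  expect_lt(abs(log2(m$mic / 0.5)), 0.5)
  # true MIC above the top concentration leaves all wells growing
  s2 <- make_dose_response(100, 8L, top_concentration = 10,
                           noise_sd = 0, seed = 1L)
  expect_true(all(inhibition_fractions(s2) < 0.5))
  expect_identical(estimate_mic(s2)$censored, ">top")
})

test_that("the difference fixture reproduces the study's structure", {
  fx <- make_difference_fixture()
  expect_identical(nrow(fx), 58L)
  expect_identical(sum(fx$present_VT1), 11L)
  # the 11 wild-type-shared and 11 mutant-shared excluded records sit in
  # the 1-5x band
  wt <- fx[fx$present_VT1, ]
  expect_true(all(wt$assembly_coverage <= 5))
  mut_cols <- paste0("present_", c("JK1", "JK2", "JK3", "JK4", "JK5",
                                   "JK6", "JK8", "JK9", "JK10", "JK11"))
  n_mut <- rowSums(as.matrix(fx[, mut_cols]))
  lc <- fx[!fx$present_VT1 & !is.na(fx$assembly_coverage) &
             fx$assembly_coverage <= 5 & n_mut >= 2, ]
  expect_identical(nrow(lc), 11L)
  # seven distinct focal-gene sites across all ten mutants
  foc <- fx[fx$contig == "Contig 10" & fx$position >= 2209 &
              fx$position <= 4041, ]
  expect_identical(length(unique(foc$position)), 7L)
  strains <- mut_cols[colSums(as.matrix(foc[, mut_cols])) > 0]
  expect_identical(length(strains), 10L)
  # determinism
  expect_identical(make_difference_fixture(), fx)
})
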