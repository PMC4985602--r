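# Difference calling thresholds, indel normalization and strain merging.

# Hand-built pileup over a short contig.
toy_pileup <- function(cs, depth_fwd, depth_rev, alt_at = integer(0),
                       alt_base = "A", alt_frac = 1) {
  L <- nchar(cs)
  cf <- matrix(0L, 4L, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  cr <- cf
  ref_idx <- match(resistseq:::seq_chars(cs), c("A", "C", "G", "T"))
  cf[cbind(ref_idx, seq_len(L))] <- depth_fwd
  cr[cbind(ref_idx, seq_len(L))] <- depth_rev
  for (p in alt_at) {
    n_alt_f <- round(depth_fwd * alt_frac)
    n_alt_r <- round(depth_rev * alt_frac)
    cf[ref_idx[p], p] <- depth_fwd - n_alt_f
    cr[ref_idx[p], p] <- depth_rev - n_alt_r
    ai <- match(alt_base, c("A", "C", "G", "T"))
    cf[ai, p] <- cf[ai, p] + n_alt_f
    cr[ai, p] <- cr[ai, p] + n_alt_r
  }
  structure(list(c1 = list(ref = cs, counts_fwd = cf, counts_rev = cr,
                           del_fwd = integer(L), del_rev = integer(L),
                           ins = data.frame(pos = integer(),
                                            allele = character(),
                                            fwd = integer(),
                                            rev = integer()))),
            class = "pileup")
}

test_that("monoallelic non-reference sites are called, reference sites not", {
  cs <- strrep("C", 60L)
  pile <- toy_pileup(cs, 25L, 25L, alt_at = 30L, alt_base = "T")
  recs <- call_differences(pile, c(c1 = cs))
  df <- as.data.frame(recs)
  expect_identical(nrow(df), 1L)
  expect_identical(df$position, 30L)
  expect_identical(df$ref_allele, "C")
  expect_identical(df$alt_allele, "T")
  expect_identical(df$type, "substitution")
  expect_identical(df$depth, 50)
  # mixed sites below the fraction threshold stay uncalled (haploid rule)
  pile2 <- toy_pileup(cs, 25L, 25L, alt_at = 30L, alt_base = "T",
                      alt_frac = 0.5)
  expect_identical(nrow(as.data.frame(call_differences(pile2,
                                                       c(c1 = cs)))), 0L)
  # depth below min_depth suppresses the call
  pile3 <- toy_pileup(cs, 4L, 4L, alt_at = 30L, alt_base = "T")
  expect_identical(nrow(as.data.frame(call_differences(pile3,
                                                       c(c1 = cs)))), 0L)
})

test_that("insertions in homopolymer runs left-normalize to the anchor", {
  g <- build_genome(seed = 4L)
  focal_contig <- g$genes$contig[g$genes$focal][1]
  specs <- resistseq:::focal_mutation_specs(focal_contig)
  inj <- inject_mutations(g, specs)
  man <- inj$manifest[inj$manifest$type == "insertion", ]
  # the codon-177 TTC->TTTC insertion: canonical left alignment anchors on
  # the base before the T run (A of the engineered GGA codon 176)
  expect_identical(unique(man$position), 2736L)
  expect_identical(unique(man$ref_allele), "A")
  expect_identical(unique(man$alt_allele), "AT")
  # and the caller reports the same representation from reads
  rs <- simulate_reads(inj$genomes$JK4,
                       read_sim_params(mean_coverage = 30, error_rate = 0,
                                       seed = 12L))
  idx <- build_index(g$contigs)
  aln <- map_reads(c(rs$r1, rs$r2), idx, g$contigs)
  recs <- as.data.frame(call_differences(build_pileup(aln, g$contigs),
                                         g$contigs))
  ins <- recs[recs$type == "insertion", ]
  expect_identical(nrow(ins), 1L)
  expect_identical(ins$position, 2736L)
  expect_identical(ins$alt_allele, "AT")
})

test_that("calling is independent of read input order", {
  g <- tiny_genome()
  cn <- names(g$contigs)[1]
  specs <- data.frame(contig = cn, position = 4000L,
                      ref_allele = substr(g$contigs[[cn]], 4000, 4000),
                      alt_allele = "N", strains = "S1")
  specs$alt_allele <- setdiff(c("A", "C", "G", "T"),
                              specs$ref_allele)[1]
  inj <- inject_mutations(g, specs)
  rs <- simulate_reads(inj$genomes$S1,
                       read_sim_params(mean_coverage = 25,
                                       error_rate = 0.005, seed = 3L))
  reads <- c(rs$r1, rs$r2)
  idx <- build_index(g$contigs)
  call_with <- function(rr) {
    aln <- map_reads(rr, idx, g$contigs)
    as.data.frame(call_differences(build_pileup(aln, g$contigs),
                                   g$contigs))
  }
  a <- call_with(reads)
  b <- call_with(rev(reads))
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
})

test_that("merge_strains collapses shared variants into presence maps", {
  rec <- function(pos, ref, alt, depth) {
    difference_records(data.frame(
      contig = "c1", position = pos, ref_allele = ref, alt_allele = alt,
      type = "substitution", depth = depth, alt_fwd = depth %/% 2,
      alt_rev = depth - depth %/% 2, alt_fraction = 0.97))
  }
  merged <- merge_strains(list(VT1 = rec(10L, "A", "G", 40L)[0, ],
                               JK4 = rec(10L, "A", "G", 40L),
                               JK5 = rec(10L, "A", "G", 55L),
                               JK6 = rec(c(10L, 99L), c("A", "C"),
                                         c("G", "T"), 35L)))
  df <- as.data.frame(merged)
  expect_identical(nrow(df), 2L)
  shared <- df[df$position == 10L, ]
  expect_true(shared$present_JK4 && shared$present_JK5 &&
                shared$present_JK6)
  expect_false(shared$present_VT1)
  expect_identical(shared$depth, 55L)  # deepest strain's metrics
  private <- df[df$position == 99L, ]
  expect_identical(sum(unlist(private[grep("present_",
                                           names(private))])), 1L)
  # conflicting reference alleles abort with the position named
  expect_error(merge_strains(list(A = rec(10L, "A", "G", 40L),
                                  B = rec(10L, "C", "G", 40L))),
               "conflicting ref")
})
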