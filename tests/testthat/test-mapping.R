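# K-mer index, seed-and-extend mapping (with the brute-force oracle), and
# pileup accounting.

test_that("the index covers every k-mer position and queries resolve", {
  idx <- build_index(c(c1 = "ACGTACGT"), k = 4L)
  expect_identical(sum(idx$end - idx$start + 1L), 5L)  # length - k + 1
  expect_identical(nrow(query_index(idx, "ACGT")), 2L)
  expect_identical(nrow(query_index(idx, "TTTT")), 0L)
  # every indexed position recovers its k-mer
  g <- tiny_genome()
  idx2 <- build_index(g$contigs, k = 21L)
  sel <- seq(1L, length(idx2$keys), by = 97L)
  for (i in sel) {
    hit <- idx2$start[i]
    cs <- g$contigs[[idx2$hit_contig[hit]]]
    p <- idx2$hit_pos[hit]
    expect_identical(substr(cs, p, p + 20L), idx2$keys[i])
  }
  expect_warning(build_index(c(tiny = "ACGT", ok = strrep("ACGT", 10L)),
                             k = 11L), "skipped")
})

test_that("exact and mutated reads map to their source locus", {
  g <- tiny_genome()
  cn <- names(g$contigs)[1]
  cs <- g$contigs[[cn]]
  idx <- build_index(g$contigs)
  r <- exact_reads(cs, c(101L, 2001L, 4001L))
  aln <- map_reads(r, idx, g$contigs)
  expect_true(all(aln$mapped))
  expect_true(all(aln$unique))
  expect_identical(aln$start, c(101L, 2001L, 4001L))
  expect_identical(aln$mismatches, c(0L, 0L, 0L))
  expect_true(all(aln$strand == "+"))
  # reverse-complement read maps to the same locus on the minus strand
  aln_rc <- map_read(revcomp(substr(cs, 2001, 2250)), idx, g$contigs)
  expect_identical(aln_rc$start, 2001L)
  expect_identical(aln_rc$strand, "-")
  # a read with three scattered mismatches still maps
  rr <- substr(cs, 3001, 3250)
  for (p in c(40L, 120L, 200L)) {
    b <- substr(rr, p, p)
    substr(rr, p, p) <- setdiff(c("A", "C", "G", "T"), b)[1]
  }
  a3 <- map_read(rr, idx, g$contigs)
  expect_identical(a3$start, 3001L)
  expect_identical(a3$mismatches, 3L)
})

test_that("reads spanning a 1-bp indel align with exactly one indel edit", {
  g <- tiny_genome()
  cn <- names(g$contigs)[1]
  cs <- g$contigs[[cn]]
  idx <- build_index(g$contigs)
  # insertion relative to the contig
  ins_read <- paste0(substr(cs, 5001, 5100), "A", substr(cs, 5101, 5249))
  ai <- map_read(ins_read, idx, g$contigs)
  expect_true(ai$mapped)
  expect_identical(ai$indel_type, "ins")
  expect_identical(ai$start, 5001L)
  # deletion relative to the contig
  del_read <- paste0(substr(cs, 4001, 4100), substr(cs, 4102, 4251))
  ad <- map_read(del_read, idx, g$contigs)
  expect_identical(ad$indel_type, "del")
  expect_identical(ad$indel_contig_pos, 4101L)
})

test_that("reads from identical repeat copies are flagged non-unique", {
  g <- tiny_genome(seed = 8L, total_length = 14000L,
                   repeats = list(n = 1L, length = 1000L, identity = 1.0))
  expect_gte(nrow(g$repeats), 2L)
  rp <- g$repeats[2, ]  # the copied interval
  cs <- g$contigs[[rp$contig]]
  r <- substr(cs, rp$start + 300L, rp$start + 549L)
  idx <- build_index(g$contigs)
  a <- map_read(r, idx, g$contigs)
  expect_true(a$mapped)
  expect_false(a$unique)
})

test_that("map_reads agrees with the exhaustive alignment oracle", {
  g <- build_genome(n_contigs = 1L, total_length = 10000L,
                    gene_density = 0.2, repeat_spec = NULL, seed = 13L)
  small <- c(c1 = substr(g$contigs[[1]], 1L, 3000L))
  idx <- build_index(small)
  set.seed(77)
  for (i in 1:12) {
    st <- sample.int(2750L, 1L)
    r <- substr(small[[1]], st, st + 249L)
    n_mm <- sample(0:3, 1L)
    if (n_mm > 0L) {
      at <- sample.int(250L, n_mm)
      for (p in at) {
        b <- substr(r, p, p)
        substr(r, p, p) <- setdiff(c("A", "C", "G", "T"), b)[1]
      }
    }
    if (i %% 3L == 0L) r <- revcomp(r)
    got <- map_read(r, idx, small)
    oracle <- brute_force_align(r, small)
    expect_true(got$mapped)
    expect_identical(got$start, oracle$start)
    expect_identical(got$mismatches, oracle$mismatches)
  }
})

test_that("pileup columns satisfy the depth and strand identities", {
  g <- tiny_genome()
  cn <- names(g$contigs)[1]
  cs <- g$contigs[[cn]]
  idx <- build_index(g$contigs)
  fwd <- exact_reads(cs, rep(1001L, 5L))
  rev <- revcomp(exact_reads(cs, rep(1001L, 5L)))
  names(rev) <- paste0("rc", 1:5)
  aln <- map_reads(c(fwd, rev), idx, g$contigs)
  pile <- build_pileup(aln, g$contigs)
  cols <- pileup_columns(pile, data.frame(contig = cn,
                                          pos = c(1001L, 1100L, 1250L)))
  expect_true(all(cols$depth == 10L))
  expect_true(all(cols$fwd == 5L & cols$rev == 5L))
  # single base counted at full depth, matching the contig
  base <- substr(cs, 1001, 1001)
  expect_identical(cols[[base]][1], 10L)
  expect_identical(cols$depth[1],
                   cols$A[1] + cols$C[1] + cols$G[1] + cols$T[1] +
                     cols$del[1])
})

test_that("simulated coverage lands within 10% of target and maps >= 99%", {
  g <- tiny_genome()
  rs <- simulate_reads(g$contigs, read_sim_params(mean_coverage = 40,
                                                  error_rate = 0.01,
                                                  seed = 31L))
  idx <- build_index(g$contigs)
  aln <- map_reads(c(rs$r1, rs$r2), idx, g$contigs)
  expect_gte(mean(aln$mapped), 0.99)
  pile <- build_pileup(aln, g$contigs)
  cn <- names(g$contigs)[1]
  depth <- colSums(pile[[cn]]$counts_fwd + pile[[cn]]$counts_rev)
  interior <- depth[800:5200]
  expect_lt(abs(mean(interior) - 40) / 40, 0.1)
})

test_that("with no errors and no mutations pileups are monoallelic", {
  g <- build_genome(n_contigs = 1L, total_length = 10000L,
                    gene_density = 0.2, repeat_spec = NULL, seed = 17L)
  rs <- simulate_reads(g$contigs, read_sim_params(mean_coverage = 20,
                                                  error_rate = 0,
                                                  seed = 17L))
  idx <- build_index(g$contigs)
  aln <- map_reads(c(rs$r1, rs$r2), idx, g$contigs)
  pile <- build_pileup(aln, g$contigs)
  recs <- call_differences(pile, g$contigs, min_alt_fraction = 0.2,
                           min_depth = 5L)
  expect_identical(nrow(as.data.frame(recs)), 0L)
})
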