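# Exclusion flags, verification, ordered accounting and gene ranking.

fake_record <- function(pos = 100L, depth = 154L, fwd = 80L, rev = 74L,
                        frac = 0.97, cov = 44, present = "JK1",
                        contig = "c1") {
  strains <- c("VT1", "JK1", "JK2", "JK3", "JK4")
  df <- data.frame(contig = contig, position = pos, ref_allele = "A",
                   alt_allele = "G", type = "substitution", depth = depth,
                   alt_fwd = fwd, alt_rev = rev, alt_fraction = frac,
                   assembly_coverage = cov)
  for (s in strains) {
    df[[paste0("present_", s)]] <-
      s %in% strsplit(present, ",")[[1]]
  }
  difference_records(df)
}

test_that("wild-type-shared flagging follows the presence map", {
  r <- rbind(fake_record(present = "VT1,JK1,JK2"),
             fake_record(pos = 200L, present = "JK1"),
             fake_record(pos = 300L, present = "VT1,JK1,JK2,JK3,JK4"))
  out <- flag_wildtype_shared(difference_records(r))
  expect_identical(out$wildtype_shared, c(TRUE, FALSE, TRUE))
})

test_that("low-coverage exclusion needs both the 1-5x band and sharing", {
  pol <- filter_policy()
  r <- rbind(fake_record(cov = 3, present = "JK1,JK2,JK3,JK4"),
             fake_record(pos = 200L, cov = 44, present = "JK1,JK2"),
             fake_record(pos = 300L, cov = 5, present = "JK1"),
             fake_record(pos = 400L, cov = NA, present = "JK1,JK2"))
  out <- flag_low_coverage_region(difference_records(r), NULL, pol)
  expect_identical(out$low_coverage_region, c(TRUE, FALSE, FALSE, FALSE))
  # a coverage track overrides record values and missing positions error
  track <- list(c1 = rep(2L, 500L))
  out2 <- flag_low_coverage_region(difference_records(r), track, pol)
  expect_identical(out2$low_coverage_region, c(TRUE, TRUE, FALSE, TRUE))
  expect_error(flag_low_coverage_region(
    difference_records(fake_record(pos = 900L)), track, pol),
    "c1:900")
})

test_that("verification checks depth, fraction and strand balance", {
  pol <- filter_policy()
  expect_true(verify_record(fake_record(depth = 154L, fwd = 80L,
                                        rev = 74L, frac = 0.97),
                            pol)$pass)
  v1 <- verify_record(fake_record(depth = 100L, fwd = 25L, rev = 25L,
                                  frac = 0.5), pol)
  expect_false(v1$pass)
  expect_true("fraction" %in% v1$reasons)
  v2 <- verify_record(fake_record(depth = 100L, fwd = 100L, rev = 0L,
                                  frac = 1), pol)
  expect_false(v2$pass)
  expect_identical(v2$reasons, "strand")
  # the binomial oracle: 100/0 is astronomically unbalanced
  expect_lt(stats::binom.test(100, 100, 0.5)$p.value, 1e-25)
  v3 <- verify_record(fake_record(depth = 12L, fwd = 6L, rev = 6L),
                      pol)
  expect_identical(v3$reasons, "depth")
})

test_that("filters attribute exclusions to the first firing reason", {
  r <- rbind(
    fake_record(present = "VT1,JK1,JK2", cov = 2),          # wt-shared
    fake_record(pos = 200L, present = "JK1,JK2", cov = 3),  # low coverage
    fake_record(pos = 300L, present = "JK1", fwd = 150L, rev = 0L,
                depth = 150L),                              # strand fail
    fake_record(pos = 400L, present = "JK1"))               # retained
  res <- apply_filters(difference_records(r))
  expect_identical(unname(res$counts),
                   c(4L, 1L, 1L, 1L, 1L))
  expect_identical(res$excluded$exclusion_reason,
                   c("wildtype_shared", "low_coverage_region",
                     "failed_verification"))
  # conservation: retained + excluded = input
  expect_identical(nrow(res$retained) + nrow(res$excluded), 4L)
  # monotone: any flagged record never reappears retained
  expect_false(any(res$retained$wildtype_shared |
                     res$retained$low_coverage_region |
                     res$retained$failed_verification))
  # empty input yields empty output and zero counts
  empty <- apply_filters(difference_records(fake_record())[0, ])
  expect_identical(unname(empty$counts), rep(0L, 5L))
})

test_that("the fixture replays to the published exclusion accounting", {
  res <- apply_filters(make_difference_fixture())
  expect_identical(unname(res$counts["input"]), 58L)
  expect_identical(unname(res$counts["wildtype_shared"]), 11L)
  expect_identical(unname(res$counts["low_coverage_region"]), 11L)
  expect_identical(unname(res$counts["retained"]), 36L)
})

test_that("gene ranking orders by distinct sites then strain coverage", {
  res <- apply_filters(make_difference_fixture())
  rk <- rank_candidate_genes(res$retained, fixture_gene_models())
  expect_identical(nrow(rk), 1L)
  expect_identical(rk$n_sites, 7L)
  expect_identical(rk$n_strains, 10L)
  # tie-break on (contig, start); empty input gives an empty ranking
  g2 <- rbind(cbind(gene_model("b", 10L, 69L, "+", "late"), focal = FALSE),
              cbind(gene_model("a", 10L, 69L, "+", "early"), focal = FALSE))
  recs <- rbind(fake_record(pos = 20L, contig = "a", present = "JK1"),
                fake_record(pos = 20L, contig = "b", present = "JK1"))
  rk2 <- rank_candidate_genes(difference_records(recs), g2)
  expect_identical(rk2$gene, c("early", "late"))
  expect_identical(nrow(rank_candidate_genes(
    difference_records(fake_record())[0, ], g2)), 0L)
})
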