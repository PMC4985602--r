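# False-positive exclusion and verification: differences shared with the
# wild type are assembly errors; differences shared by several mutants in
# low-assembly-coverage regions are unreliable consensus; survivors must
# show deep, strand-balanced, near-fixed alternate support.

#' Filtering policy
#'
#' @param low_coverage_max Assembly coverage at/below which a region is
#'   unreliable (default 5, the 1-5x band).
#' @param verify_min_depth Minimum read depth at a verified site
#'   (default 20).
#' @param verify_min_alt_fraction Minimum alternate allele fraction
#'   (default 0.9, i.e. present in 90-100% of the reads).
#' @param strand_balance_alpha Significance level of the two-sided
#'   binomial(0.5) test on forward vs reverse alternate support
#'   (default 0.01).
#' @param shared_strain_min Number of mutant strains that must share a
#'   low-coverage difference before it is excluded (default 2).
#' @return A list of class `filter_policy`.
#' @export
filter_policy <- function(low_coverage_max = 5L, verify_min_depth = 20L,
                          verify_min_alt_fraction = 0.9,
                          strand_balance_alpha = 0.01,
                          shared_strain_min = 2L) {
  if (verify_min_alt_fraction <= 0 || verify_min_alt_fraction > 1) {
    stop("verify_min_alt_fraction must be in (0, 1]")
  }
  if (low_coverage_max < 1L) stop("low_coverage_max must be >= 1")
  structure(list(low_coverage_max = low_coverage_max,
                 verify_min_depth = verify_min_depth,
                 verify_min_alt_fraction = verify_min_alt_fraction,
                 strand_balance_alpha = strand_balance_alpha,
                 shared_strain_min = shared_strain_min),
            class = "filter_policy")
}

#' @export
print.filter_policy <- function(x, ...) {
  cat("Filter policy: low coverage <=", x$low_coverage_max,
      "| verify depth >=", x$verify_min_depth, ", fraction >=",
      x$verify_min_alt_fraction, ", strand alpha", x$strand_balance_alpha,
      "| shared strains >=", x$shared_strain_min, "\n")
  invisible(x)
}

# Wild-type column name among the present_* columns.
wildtype_column <- function(records, wildtype = "VT1") {
  col <- paste0("present_", wildtype)
  if (!col %in% names(records)) {
    stop("no presence column for wild type '", wildtype, "'")
  }
  col
}

#' Flag differences shared with the wild type
#'
#' A difference also seen when the wild-type reads are compared against the
#' assembly built from them indicates an assembly error, not a mutation.
#'
#' @param records Merged [difference_records()] with presence columns.
#' @param wildtype Wild-type strain label (default "VT1").
#' @return The records with `wildtype_shared` set.
#' @export
flag_wildtype_shared <- function(records, wildtype = "VT1") {
  col <- wildtype_column(records, wildtype)
  records$wildtype_shared <- records[[col]]
  records
}

#' Flag shared differences in low-coverage assembly regions
#'
#' Differences reported in several mutant genomes that localize to regions
#' of the assembly with unreliable (1-5x) coverage are excluded as
#' consensus errors. A low-coverage difference private to a single mutant
#' is not flagged by this rule.
#'
#' @param records Merged [difference_records()].
#' @param coverage_track Named list of per-position assembly-coverage
#'   vectors, or NULL to use the records' own `assembly_coverage` values.
#' @param policy A [filter_policy()].
#' @param wildtype Wild-type strain label.
#' @return The records with `low_coverage_region` set.
#' @export
flag_low_coverage_region <- function(records, coverage_track = NULL,
                                     policy = filter_policy(),
                                     wildtype = "VT1") {
  if (!is.null(coverage_track)) {
    cov <- mapply(function(cn, p) {
      v <- coverage_track[[cn]]
      if (is.null(v) || p > length(v)) {
        stop("no assembly coverage for ", cn, ":", p)
      }
      v[p]
    }, records$contig, records$position)
    records$assembly_coverage <- as.numeric(cov)
  }
  mut_cols <- setdiff(grep("^present_", names(records), value = TRUE),
                      paste0("present_", wildtype))
  n_mut <- if (length(mut_cols)) {
    rowSums(as.matrix(records[, mut_cols, drop = FALSE]))
  } else {
    rep(0L, nrow(records))
  }
  lowcov <- !is.na(records$assembly_coverage) &
    records$assembly_coverage <= policy$low_coverage_max
  records$low_coverage_region <- lowcov & n_mut >= policy$shared_strain_min
  records
}

#' Verify a difference record
#'
#' A record passes when its site depth and alternate allele fraction clear
#' the policy minima and a two-sided binomial(0.5) test does not reject
#' equal strand representation of the alternate-supporting reads.
#'
#' @param record One record (one-row data frame or list with depth,
#'   alt_fraction, alt_fwd, alt_rev).
#' @param policy A [filter_policy()].
#' @return List with `pass` (logical) and `reasons` (character vector,
#'   empty on pass).
#' @export
verify_record <- function(record, policy = filter_policy()) {
  reasons <- character(0)
  if (is.na(record$depth) || record$depth < policy$verify_min_depth) {
    reasons <- c(reasons, "depth")
  }
  if (is.na(record$alt_fraction) ||
      record$alt_fraction < policy$verify_min_alt_fraction) {
    reasons <- c(reasons, "fraction")
  }
  fwd <- record$alt_fwd
  rev <- record$alt_rev
  if (is.na(fwd) || is.na(rev)) {
    reasons <- c(reasons, "strand")
  } else if (fwd + rev > 0) {
    p <- stats::binom.test(fwd, fwd + rev, p = 0.5)$p.value
    if (p < policy$strand_balance_alpha) reasons <- c(reasons, "strand")
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Apply the full exclusion and verification pipeline
#'
#' Flags are evaluated in order (wild-type-shared, then low-coverage
#' shared, then verification) and every excluded record is attributed to
#' the first reason that fires, so the exclusion accounting is
#' well-defined.
#'
#' @param records Merged [difference_records()].
#' @param coverage_track Optional assembly-coverage track (see
#'   [flag_low_coverage_region()]).
#' @param policy A [filter_policy()].
#' @param wildtype Wild-type strain label.
#' @return List of class `filter_result`: `retained` records, `excluded`
#'   records with an `exclusion_reason` column, `counts` (named vector
#'   input/wildtype_shared/low_coverage_region/failed_verification/
#'   retained).
#' @export
apply_filters <- function(records, coverage_track = NULL,
                          policy = filter_policy(), wildtype = "VT1") {
  if (nrow(records) == 0L) {
    return(structure(list(retained = records,
                          excluded = cbind(records,
                                           exclusion_reason = character(0)),
                          counts = c(input = 0L, wildtype_shared = 0L,
                                     low_coverage_region = 0L,
                                     failed_verification = 0L,
                                     retained = 0L)),
                     class = "filter_result"))
  }
  records <- flag_wildtype_shared(records, wildtype)
  records <- flag_low_coverage_region(records, coverage_track, policy,
                                      wildtype)
  verify <- lapply(seq_len(nrow(records)), function(i)
    verify_record(records[i, ], policy))
  records$failed_verification <- !vapply(verify, `[[`, logical(1), "pass")
  reason <- rep(NA_character_, nrow(records))
  reason[records$failed_verification] <- "failed_verification"
  reason[records$low_coverage_region] <- "low_coverage_region"
  reason[records$wildtype_shared] <- "wildtype_shared"
  retained <- records[is.na(reason), , drop = FALSE]
  excluded <- records[!is.na(reason), , drop = FALSE]
  excluded$exclusion_reason <- reason[!is.na(reason)]
  counts <- c(input = nrow(records),
              wildtype_shared = sum(reason == "wildtype_shared",
                                    na.rm = TRUE),
              low_coverage_region = sum(reason == "low_coverage_region",
                                        na.rm = TRUE),
              failed_verification = sum(reason == "failed_verification",
                                        na.rm = TRUE),
              retained = nrow(retained))
  structure(list(retained = retained, excluded = excluded,
                 counts = counts),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat("Difference filtering:", x$counts["input"], "in ->",
      x$counts["retained"], "retained (",
      x$counts["wildtype_shared"], "wild-type-shared,",
      x$counts["low_coverage_region"], "low-coverage shared,",
      x$counts["failed_verification"], "failed verification )\n")
  invisible(x)
}

#' Rank candidate genes by mutation recurrence
#'
#' Orders genes by the number of distinct mutated sites they contain and by
#' the number of strains carrying at least one mutation in them; ties break
#' on (contig, start) for reproducibility.
#'
#' @param retained Retained records from [apply_filters()].
#' @param genes Gene-model data frame.
#' @param wildtype Wild-type strain label to exclude from strain counts.
#' @return Data frame gene/contig/start/end/n_sites/n_strains/strains,
#'   ordered best first.
#' @export
rank_candidate_genes <- function(retained, genes, wildtype = "VT1") {
  if (nrow(retained) == 0L || nrow(genes) == 0L) {
    return(data.frame(gene = character(), contig = character(),
                      start = integer(), end = integer(),
                      n_sites = integer(), n_strains = integer(),
                      strains = character(), stringsAsFactors = FALSE))
  }
  mut_cols <- setdiff(grep("^present_", names(retained), value = TRUE),
                      paste0("present_", wildtype))
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    inside <- retained$contig == g$contig &
      retained$position >= g$start & retained$position <= g$end
    if (!any(inside)) next
    sub <- retained[inside, , drop = FALSE]
    pres <- as.matrix(sub[, mut_cols, drop = FALSE])
    strains <- sub("^present_", "", mut_cols)[colSums(pres) > 0L]
    rows[[length(rows) + 1L]] <- data.frame(
      gene = g$name, contig = g$contig, start = g$start, end = g$end,
      n_sites = length(unique(sub$position)),
      n_strains = length(strains),
      strains = paste(sort(strains), collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(gene = character(), contig = character(),
                      start = integer(), end = integer(),
                      n_sites = integer(), n_strains = integer(),
                      strains = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_sites, -out$n_strains, out$contig, out$start), ]
  rownames(out) <- NULL
  out
}
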