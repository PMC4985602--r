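# Candidate polymorphism calling from pileups: one DifferenceRecord per
# site where the majority non-reference allele clears the calling
# thresholds. Calling is deliberately generous (fraction 0.8); the paper's
# decision point is the downstream filter/verification stage.

#' Construct / validate a difference-record table
#'
#' @param df Data frame with at least contig, position, ref_allele,
#'   alt_allele, type, depth, alt_fwd, alt_rev, alt_fraction; missing
#'   metadata columns (assembly_coverage, filter flags, annotation) are
#'   added.
#' @return The validated data frame with class `difference_records`.
#' @export
difference_records <- function(df) {
  need <- c("contig", "position", "ref_allele", "alt_allele", "type",
            "depth", "alt_fwd", "alt_rev", "alt_fraction")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!all(df$type %in% c("substitution", "insertion", "deletion"))) {
    stop("type must be substitution/insertion/deletion")
  }
  if (any(df$alt_fraction < 0 | df$alt_fraction > 1, na.rm = TRUE)) {
    stop("alt_fraction outside [0, 1]")
  }
  if (any(df$alt_fwd + df$alt_rev > df$depth, na.rm = TRUE)) {
    stop("alt-supporting reads exceed depth")
  }
  n <- nrow(df)
  if (!"assembly_coverage" %in% names(df)) {
    df$assembly_coverage <- rep(NA_real_, n)
  }
  for (fl in c("wildtype_shared", "low_coverage_region",
               "failed_verification")) {
    if (!fl %in% names(df)) df[[fl]] <- rep(FALSE, n)
  }
  if (!"annotation" %in% names(df)) df$annotation <- rep(NA_character_, n)
  if (!inherits(df, "difference_records")) {
    class(df) <- c("difference_records", class(df))
  }
  df
}

#' @export
print.difference_records <- function(x, ...) {
  cat("Difference records:", nrow(x), "sites")
  pres <- grep("^present_", names(x), value = TRUE)
  if (length(pres)) cat(" across", length(pres), "strains")
  cat("\n")
  flags <- c(wildtype_shared = sum(x$wildtype_shared),
             low_coverage = sum(x$low_coverage_region),
             failed_verification = sum(x$failed_verification))
  cat("  flags:", paste(names(flags), flags, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Call differences between a read set and the draft contigs
#'
#' Emits a record wherever the majority non-reference allele reaches
#' `min_alt_fraction` of the depth at a site with at least `min_depth`
#' reads. Alleles are reported on the contig forward strand; indels are
#' left-normalized with the anchor-base convention (position of the base
#' before the event, ref and alt sharing their first base). Mixed sites
#' below the fraction threshold are not called: the organisms are haploid
#' and sub-clonal signal is treated as absence.
#'
#' @param pile A [build_pileup()] result.
#' @param contigs Named contig sequences (the draft the pileup was built
#'   against).
#' @param min_alt_fraction Minimum alternate allele fraction (default 0.8).
#' @param min_depth Minimum read depth (default 10).
#' @param coverage_track Optional named list of assembly-coverage vectors;
#'   when given, `assembly_coverage` is populated.
#' @return A [difference_records()] data frame.
#' @export
call_differences <- function(pile, contigs, min_alt_fraction = 0.8,
                             min_depth = 10L, coverage_track = NULL) {
  rows <- list()
  for (cn in names(pile)) {
    p <- pile[[cn]]
    cs <- as.character(contigs[[cn]])
    L <- nchar(cs)
    tot <- p$counts_fwd + p$counts_rev
    del <- p$del_fwd + p$del_rev
    depth <- colSums(tot) + del
    ref_idx <- match(seq_chars(cs), DNA_BASES)
    alt_counts <- tot
    sel <- !is.na(ref_idx)
    alt_counts[cbind(ref_idx[sel], which(sel))] <- 0L
    top_idx <- max.col(t(alt_counts), ties.method = "first")
    top_cnt <- alt_counts[cbind(top_idx, seq_len(L))]

    # substitutions
    frac <- ifelse(depth > 0, top_cnt / depth, 0)
    hit <- which(depth >= min_depth & frac >= min_alt_fraction)
    for (i in hit) {
      rows[[length(rows) + 1L]] <- data.frame(
        contig = cn, position = i,
        ref_allele = substr(cs, i, i), alt_allele = DNA_BASES[top_idx[i]],
        type = "substitution", depth = depth[i],
        alt_fwd = p$counts_fwd[top_idx[i], i],
        alt_rev = p$counts_rev[top_idx[i], i],
        alt_fraction = frac[i], stringsAsFactors = FALSE)
    }
    # reads spanning the closed interval [a, b]: reads covering b minus
    # those that started after a; used as the informative denominator for
    # indels, since a read ending inside a homopolymer run cannot attest
    # an indel of that run's base
    spanning <- function(a, b) {
      a <- max(a, 1L); b <- min(b, L)
      if (is.null(p$starts)) return(depth[b])
      depth[b] - sum(p$starts[(a + 1L):b])
    }
    run_end_of <- function(from, unit) {
      e <- from
      while (e < L && substr(cs, e + 1L, e + 1L) == unit) e <- e + 1L
      e
    }
    # indels: normalize first, pool support across equivalent anchors,
    # then measure the alternate fraction over informative reads only
    emit_indel <- function(nd, type) {
      key <- paste(nd$position, nd$ref_allele, nd$alt_allele)
      for (k in unique(key)) {
        sub <- nd[key == k, , drop = FALSE]
        pos <- sub$position[1L]
        n_fwd <- sum(sub$fwd); n_rev <- sum(sub$rev)
        n_alt <- n_fwd + n_rev
        unit <- if (type == "insertion") {
          substr(sub$alt_allele[1L], 2L, 2L)
        } else {
          substr(sub$ref_allele[1L], 2L, 2L)
        }
        b <- run_end_of(pos + 1L, unit) + 1L
        d <- max(spanning(pos, b), n_alt)
        if (d >= min_depth && n_alt / d >= min_alt_fraction) {
          rows[[length(rows) + 1L]] <<- data.frame(
            contig = cn, position = pos, ref_allele = sub$ref_allele[1L],
            alt_allele = sub$alt_allele[1L], type = type,
            depth = d, alt_fwd = n_fwd, alt_rev = n_rev,
            alt_fraction = n_alt / d, stringsAsFactors = FALSE)
        }
      }
    }
    if (nrow(p$ins) > 0L) {
      nd <- do.call(rbind, lapply(seq_len(nrow(p$ins)), function(i) {
        pos <- p$ins$pos[i]
        anchor <- substr(cs, pos, pos)
        nrm <- normalize_indel(cs, pos, anchor,
                               paste0(anchor, p$ins$allele[i]))
        data.frame(position = nrm$position, ref_allele = nrm$ref,
                   alt_allele = nrm$alt, fwd = p$ins$fwd[i],
                   rev = p$ins$rev[i], stringsAsFactors = FALSE)
      }))
      emit_indel(nd, "insertion")
    }
    dhit <- which(del > 0L)
    if (length(dhit) > 0L) {
      nd <- do.call(rbind, lapply(dhit, function(i) {
        anchor_pos <- max(1L, i - 1L)
        nrm <- normalize_indel(cs, anchor_pos,
                               substr(cs, anchor_pos, i),
                               substr(cs, anchor_pos, anchor_pos))
        data.frame(position = nrm$position, ref_allele = nrm$ref,
                   alt_allele = nrm$alt, fwd = p$del_fwd[i],
                   rev = p$del_rev[i], stringsAsFactors = FALSE)
      }))
      emit_indel(nd, "deletion")
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig = character(), position = integer(),
               ref_allele = character(), alt_allele = character(),
               type = character(), depth = numeric(), alt_fwd = numeric(),
               alt_rev = numeric(), alt_fraction = numeric(),
               stringsAsFactors = FALSE)
  out <- out[order(out$contig, out$position), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(coverage_track) && nrow(out) > 0L) {
    out$assembly_coverage <- mapply(function(cn, p)
      coverage_track[[cn]][p], out$contig, out$position)
  }
  difference_records(out)
}

#' Merge per-strain difference records
#'
#' Records identical in (contig, position, ref, alt, type) across strains
#' collapse to one row with a per-strain presence map; metrics are taken
#' from the deepest strain and the full per-strain detail is kept in the
#' `detail` attribute.
#'
#' @param per_strain_records Named list: strain label -> records from
#'   [call_differences()] against the same contigs.
#' @return A [difference_records()] table with logical `present_<strain>`
#'   columns.
#' @export
merge_strains <- function(per_strain_records) {
  strains <- names(per_strain_records)
  if (is.null(strains) || any(strains == "")) {
    stop("per_strain_records must be a named list")
  }
  all <- do.call(rbind, lapply(strains, function(s) {
    df <- as.data.frame(per_strain_records[[s]])
    if (nrow(df) == 0L) return(NULL)
    df$strain <- s
    df
  }))
  if (is.null(all) || nrow(all) == 0L) {
    out <- difference_records(data.frame(
      contig = character(), position = integer(), ref_allele = character(),
      alt_allele = character(), type = character(), depth = numeric(),
      alt_fwd = numeric(), alt_rev = numeric(), alt_fraction = numeric()))
    for (s in strains) out[[paste0("present_", s)]] <- logical(0)
    return(out)
  }
  # conflicting ref alleles at one position are a caller inconsistency
  key_pos <- paste(all$contig, all$position, all$type)
  refs_by_pos <- tapply(all$ref_allele, key_pos,
                        function(x) length(unique(x)))
  if (any(refs_by_pos > 1L)) {
    bad <- names(refs_by_pos)[refs_by_pos > 1L][1L]
    stop("conflicting ref alleles at ", bad)
  }
  key <- paste(all$contig, all$position, all$ref_allele, all$alt_allele,
               all$type, sep = "\r")
  first_by_depth <- order(-all$depth)
  rep_row <- first_by_depth[!duplicated(key[first_by_depth])]
  out <- all[rep_row, c("contig", "position", "ref_allele", "alt_allele",
                        "type", "depth", "alt_fwd", "alt_rev",
                        "alt_fraction",
                        intersect("assembly_coverage", names(all))),
             drop = FALSE]
  out_key <- key[rep_row]
  for (s in strains) {
    out[[paste0("present_", s)]] <- out_key %in% key[all$strain == s]
  }
  out <- out[order(out$contig, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out <- difference_records(out)
  attr(out, "detail") <- all
  out
}

#' Strain labels of a merged record table
#'
#' @param records A merged [difference_records()] table.
#' @return Character vector of strain labels (from `present_*` columns).
#' @export
record_strains <- function(records) {
  sub("^present_", "", grep("^present_", names(records), value = TRUE))
}
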