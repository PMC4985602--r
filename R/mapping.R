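# Seed-and-extend read mapping against draft contigs and pileup
# construction. The mapper collects exact k-mer seed hits on a shared
# diagonal, verifies candidates by ungapped comparison, and falls back to an
# edit-aware scan allowing at most one 1-bp indel. Multi-locus score ties
# clear the unique flag; pileups use unique alignments only by default.

#' Build a k-mer index of contig sequences
#'
#' Indexes every forward-strand k-mer of every contig. Reverse-complement
#' reads are handled at query time by also seeding the reverse complement of
#' the read.
#'
#' @param contigs Named character vector of contig sequences.
#' @param k K-mer size (default 21; sizes below ~11 are only sensible for
#'   toy sequences).
#' @return List of class `kmer_index` with `k`, `keys` (unique k-mers),
#'   `hits` (list parallel to keys: integer matrix columns contig_id/pos),
#'   `contig_names`.
#' @export
build_index <- function(contigs, k = 21L) {
  if (k < 2L) stop("k must be >= 2")
  if (length(contigs) == 0L) stop("no contigs to index")
  kmers <- character(0)
  contig_id <- integer(0)
  pos <- integer(0)
  for (i in seq_along(contigs)) {
    s <- as.character(contigs[[i]])
    L <- nchar(s)
    if (L < k) {
      warning("contig ", names(contigs)[i], " shorter than k = ", k,
              "; skipped")
      next
    }
    p <- seq_len(L - k + 1L)
    kmers <- c(kmers, substring(s, p, p + k - 1L))
    contig_id <- c(contig_id, rep.int(i, length(p)))
    pos <- c(pos, p)
  }
  keys <- unique(kmers)
  grp <- match(kmers, keys)
  ord <- order(grp)
  bounds <- c(0L, cumsum(tabulate(grp, nbins = length(keys))))
  hits_contig <- contig_id[ord]
  hits_pos <- pos[ord]
  structure(list(k = as.integer(k), keys = keys,
                 start = bounds[-length(bounds)] + 1L,
                 end = bounds[-1L],
                 hit_contig = hits_contig, hit_pos = hits_pos,
                 contig_names = names(contigs)),
            class = "kmer_index")
}

#' Query a k-mer against the index
#'
#' @param index A [build_index()] result.
#' @param kmer K-mer string.
#' @return Data frame contig/pos (0 rows when absent).
#' @export
query_index <- function(index, kmer) {
  i <- match(kmer, index$keys)
  if (is.na(i)) {
    return(data.frame(contig = character(), pos = integer()))
  }
  sel <- index$start[i]:index$end[i]
  data.frame(contig = index$contig_names[index$hit_contig[sel]],
             pos = index$hit_pos[sel], stringsAsFactors = FALSE)
}

# Ungapped mismatch count of read (oriented) against contig at start;
# returns NA when the alignment would leave the contig.
ungapped_mismatches <- function(read, contig_seq, start) {
  rl <- nchar(read)
  if (start < 1L || start + rl - 1L > nchar(contig_seq)) return(NA_integer_)
  count_mismatches(read, substr(contig_seq, start, start + rl - 1L))
}

# Best single 1-bp-indel alignment of read at candidate start, found in
# O(read length) per start via prefix/suffix mismatch sums.
# type "ins": read has an extra base (contig span rl-1);
# type "del": contig has an extra base (contig span rl+1).
# Returns list(mismatches, type, read_pos, contig_pos, allele) or NULL.
indel_alignment <- function(read, contig_seq, start) {
  rl <- nchar(read)
  L <- nchar(contig_seq)
  best <- NULL
  rr <- as.integer(charToRaw(read))
  # insertion in read at read position i (i = 2..rl-1): read[i] is extra;
  # read[1..i-1] aligns to ref[1..i-1], read[i+1..rl] to ref[i..rl-1]
  if (start >= 1L && start + rl - 2L <= L) {
    ref <- as.integer(charToRaw(substr(contig_seq, start,
                                       start + rl - 2L)))
    pre <- cumsum(rr[seq_len(rl - 1L)] != ref)            # P[j], j=1..rl-1
    sufv <- rev(cumsum(rev(rr[2:rl] != ref)))             # S[j], j=2..rl
    i <- 2:(rl - 1L)
    mm <- pre[i - 1L] + sufv[i]                            # S indexed at i+1
    # sufv vector position k corresponds to read index k+1, so S[i+1] is
    # sufv[i]; see definitions above
    bi <- i[which.min(mm)]
    best <- list(mismatches = unname(mm[bi - 1L]), type = "ins",
                 read_pos = bi, contig_pos = start + bi - 2L,
                 allele = substr(read, bi, bi))
  }
  # deletion from read: contig base at start+i-1 missing (i = 2..rl);
  # read[1..i-1] aligns to ref[1..i-1], read[i..rl] to ref[i+1..rl+1]
  if (start >= 1L && start + rl <= L) {
    ref <- as.integer(charToRaw(substr(contig_seq, start, start + rl)))
    pre <- cumsum(rr != ref[seq_len(rl)])                  # P[j], j=1..rl
    sufv <- rev(cumsum(rev(rr != ref[2:(rl + 1L)])))       # S2[j], j=1..rl
    i <- 2:rl
    mm <- pre[i - 1L] + c(sufv, 0L)[i]
    bi <- i[which.min(mm)]
    cand <- list(mismatches = unname(mm[bi - 1L]), type = "del",
                 read_pos = bi, contig_pos = start + bi - 1L,
                 allele = rawToChar(as.raw(ref[bi])))
    if (is.null(best) || cand$mismatches < best$mismatches) best <- cand
  }
  best
}

#' Map reads to contigs
#'
#' Seed-and-extend mapping: exact k-mer seeds at regular offsets vote for a
#' (contig, diagonal) locus in both orientations; the winning locus is
#' verified by ungapped comparison and, where the seed diagonals indicate
#' it, by a 1-bp-indel-aware scan. The unique flag is cleared when a second
#' locus ties the best score. Reads extending past a contig edge are left
#' unmapped.
#'
#' @param reads Named character vector of reads (uniform length).
#' @param index A [build_index()] of the target contigs.
#' @param contigs The same named contig sequences.
#' @param max_mismatches Maximum mismatches per read (default 5).
#' @return Data frame of class `read_alignments`: read, contig, start,
#'   strand, mismatches, indel_type (NA/ins/del), indel_read_pos,
#'   indel_contig_pos, indel_allele, unique, mapped, seq (read oriented to
#'   the contig forward strand).
#' @export
map_reads <- function(reads, index, contigs, max_mismatches = 5L) {
  k <- index$k
  n <- length(reads)
  if (n == 0L) stop("no reads supplied")
  rl <- unique(nchar(reads))
  if (length(rl) != 1L) stop("reads must have uniform length")
  if (rl < k) stop("read length ", rl, " shorter than k = ", k)
  offs <- unique(c(seq(1L, rl - k + 1L, by = k), rl - k + 1L))
  no <- length(offs)

  oriented <- c(reads, revcomp(reads))
  rid <- rep(seq_len(2L * n), each = no)
  off <- rep(offs, times = 2L * n)
  km <- substring(rep(oriented, each = no), off, off + k - 1L)
  mi <- match(km, index$keys)
  keep <- !is.na(mi)
  rid <- rid[keep]; off <- off[keep]; mi <- mi[keep]
  cnt <- index$end[mi] - index$start[mi] + 1L
  sel <- sequence(cnt, from = index$start[mi])
  DT <- data.table::data.table(
    rid = rep.int(rid, cnt), off = rep.int(off, cnt),
    contig = index$hit_contig[sel], cpos = index$hit_pos[sel])
  DT[, diag := cpos - off + 1L]
  sup <- DT[, list(nseed = .N, min_off = min(off)),
            by = c("rid", "contig", "diag")]
  # merge adjacent diagonals (a single 1-bp indel splits a locus in two)
  for (d in c(-1L, 1L)) {
    nb <- sup[, list(rid, contig, diag = diag + d, add = nseed)]
    sup <- merge(sup, nb, by = c("rid", "contig", "diag"),
                 all.x = TRUE, allow.cartesian = FALSE)
    sup[is.na(add), add := 0L]
    data.table::setnames(sup, "add", paste0("add", d))
  }
  sup[, total := nseed + `add-1` + add1]
  data.table::setorderv(sup, c("rid", "total", "contig", "diag"),
                        order = c(1L, -1L, 1L, 1L))
  best <- sup[, utils::head(.SD, 1L), by = "rid"]
  # second-best support at a distinct locus (diagonal differing by > 1)
  sup2 <- merge(sup, best[, list(rid, bcontig = contig, bdiag = diag)],
                by = "rid")
  sup2 <- sup2[contig != bcontig | abs(diag - bdiag) > 1L]
  data.table::setorderv(sup2, c("rid", "total"), order = c(1L, -1L))
  second <- sup2[, list(second = total[1L], scontig = contig[1L],
                        sdiag = diag[1L]), by = "rid"]
  best <- merge(best, second, by = "rid", all.x = TRUE)
  best[is.na(second), second := 0L]
  # indel suspicion: a neighbouring diagonal also carries seeds
  best[, suspect := `add-1` > 0L | add1 > 0L]

  contig_seqs <- vapply(contigs, as.character, character(1))
  out <- data.frame(
    read = names(reads), contig = NA_character_, start = NA_integer_,
    strand = NA_character_, mismatches = NA_integer_,
    indel_type = NA_character_, indel_read_pos = NA_integer_,
    indel_contig_pos = NA_integer_, indel_allele = NA_character_,
    unique = NA, mapped = FALSE, seq = NA_character_,
    stringsAsFactors = FALSE)

  b_rid <- best$rid
  b_contig <- best$contig
  b_diag <- best$diag
  b_suspect <- best$suspect
  b_second <- best$second
  b_total <- best$total
  b_scontig <- best$scontig
  b_sdiag <- best$sdiag

  for (j in seq_along(b_rid)) {
    r <- b_rid[j]
    ridx <- if (r > n) r - n else r
    strand <- if (r > n) "-" else "+"
    # prefer the orientation with more support when both were seeded: each
    # oriented copy is its own rid, so the weaker orientation of the same
    # read simply loses at per-read reconciliation below
    rseq <- oriented[r]
    cs <- contig_seqs[b_contig[j]]
    # candidate start: for an insertion the right-hand seeds sit on
    # diag-1, for a deletion on diag+1; alignment start is the diagonal
    # holding the leftmost seed
    start <- b_diag[j]
    mm <- ungapped_mismatches(rseq, cs, start)
    res <- NULL
    # an ungapped alignment with <= 1 mismatch cannot be beaten by a
    # gapped one (one indel costs 1); anything worse gets the edit-aware
    # comparison, which also catches indels too close to a read end to
    # leave seeds on a second diagonal
    if (!is.na(mm) && mm <= 1L && !b_suspect[j]) {
      res <- list(start = start, mism = mm, indel = NULL)
    } else {
      cand_res <- list()
      if (!is.na(mm)) cand_res[["M"]] <- list(start = start, mism = mm,
                                              indel = NULL)
      for (st in unique(c(start, start - 1L, start + 1L))) {
        ia <- indel_alignment(rseq, cs, st)
        if (!is.null(ia)) {
          key <- paste0("I", st)
          cand_res[[key]] <- list(start = st, mism = ia$mismatches,
                                  indel = ia)
        }
      }
      if (length(cand_res)) {
        scores <- vapply(cand_res, function(x)
          x$mism + if (is.null(x$indel)) 0L else 1L, numeric(1))
        bestc <- cand_res[[which.min(scores)]]
        if (bestc$mism <= max_mismatches) res <- bestc
      }
    }
    if (is.null(res)) next
    # when a rival locus carries comparable seed support, compare actual
    # alignment scores so exact repeat copies clear the unique flag
    score <- res$mism + if (is.null(res$indel)) 0L else 1L
    uniq_here <- b_second[j] < b_total[j]
    if (!uniq_here && !is.na(b_scontig[j])) {
      mm2 <- ungapped_mismatches(rseq, contig_seqs[b_scontig[j]],
                                 b_sdiag[j])
      uniq_here <- !is.na(mm2) && mm2 > score
    }
    prev <- out$mismatches[ridx]
    prev_score <- if (is.na(prev)) Inf else
      prev + if (is.na(out$indel_type[ridx])) 0L else 1L
    if (score < prev_score ||
        (score == prev_score && is.na(out$contig[ridx]))) {
      uniq <- uniq_here
      if (score == prev_score && !is.na(prev)) uniq <- FALSE
      out$contig[ridx] <- index$contig_names[b_contig[j]]
      out$start[ridx] <- res$start
      out$strand[ridx] <- strand
      out$mismatches[ridx] <- res$mism
      out$unique[ridx] <- uniq
      out$mapped[ridx] <- TRUE
      out$seq[ridx] <- rseq
      if (!is.null(res$indel)) {
        out$indel_type[ridx] <- res$indel$type
        out$indel_read_pos[ridx] <- res$indel$read_pos
        out$indel_contig_pos[ridx] <- res$indel$contig_pos
        out$indel_allele[ridx] <- res$indel$allele
      } else {
        out$indel_type[ridx] <- NA_character_
        out$indel_read_pos[ridx] <- NA_integer_
        out$indel_contig_pos[ridx] <- NA_integer_
        out$indel_allele[ridx] <- NA_character_
      }
    } else if (score == prev_score) {
      out$unique[ridx] <- FALSE
    }
  }
  class(out) <- c("read_alignments", class(out))
  out
}

#' Map a single read
#'
#' Convenience wrapper around [map_reads()] for one read.
#'
#' @inheritParams map_reads
#' @param read A single read sequence.
#' @return One-row alignment data frame (see [map_reads()]); `mapped` is
#'   FALSE when no locus passes.
#' @export
map_read <- function(read, index, contigs, max_mismatches = 5L) {
  r <- c(read1 = read)
  map_reads(r, index, contigs, max_mismatches)
}

#' Build per-position pileups from alignments
#'
#' Accumulates per-base counts split by strand plus insertion/deletion
#' evidence for every contig position. Multi-mapping reads are excluded by
#' default, mirroring the exclusion of repeat-confounded evidence.
#'
#' @param alignments A [map_reads()] result.
#' @param contigs Named contig sequences.
#' @param unique_only Drop alignments with `unique = FALSE` (default TRUE).
#' @return List of class `pileup`: per contig a list with `ref`,
#'   `counts_fwd`/`counts_rev` (4 x L integer matrices, rows ACGT),
#'   `del_fwd`/`del_rev` (integer vectors), `ins` (data frame
#'   pos/allele/fwd/rev).
#' @export
build_pileup <- function(alignments, contigs, unique_only = TRUE) {
  aln <- alignments[alignments$mapped, , drop = FALSE]
  if (unique_only) aln <- aln[aln$unique, , drop = FALSE]
  base_lookup <- integer(256)
  base_lookup[as.integer(charToRaw("ACGT"))] <- 1:4
  out <- list()
  for (cn in names(contigs)) {
    cs <- as.character(contigs[[cn]])
    L <- nchar(cs)
    counts <- list("+" = matrix(0L, 4L, L), "-" = matrix(0L, 4L, L))
    dels <- list("+" = integer(L), "-" = integer(L))
    starts <- integer(L)
    ins_rows <- list()
    ca <- aln[aln$contig == cn, , drop = FALSE]
    # reject alignments that would run past the contig end
    span <- nchar(ca$seq) + ifelse(is.na(ca$indel_type), 0L,
                                   ifelse(ca$indel_type == "ins", -1L, 1L))
    bad <- ca$start + span - 1L > L | ca$start < 1L
    if (any(bad)) {
      warning(sum(bad), " alignment(s) past the end of ", cn, " rejected")
      ca <- ca[!bad, , drop = FALSE]
    }
    if (nrow(ca) > 0L) starts <- tabulate(ca$start, nbins = L)
    for (strand in c("+", "-")) {
      sa <- ca[ca$strand == strand & is.na(ca$indel_type), , drop = FALSE]
      if (nrow(sa) > 0L) {
        rls <- nchar(sa$seq)
        pos <- sequence(rls, from = sa$start)
        raw <- as.integer(charToRaw(paste(sa$seq, collapse = "")))
        bi <- base_lookup[raw]
        ok <- bi > 0L
        counts[[strand]] <- counts[[strand]] +
          matrix(tabulate((pos[ok] - 1L) * 4L + bi[ok], nbins = 4L * L),
                 nrow = 4L)
      }
    }
    # indel-bearing alignments one by one (they are few)
    ia <- ca[!is.na(ca$indel_type), , drop = FALSE]
    for (i in seq_len(nrow(ia))) {
      strand <- ia$strand[i]
      rseq <- ia$seq[i]
      rl <- nchar(rseq)
      st <- ia$start[i]
      if (ia$indel_type[i] == "ins") {
        ip <- ia$indel_read_pos[i]
        left <- substr(rseq, 1L, ip - 1L)
        right <- substr(rseq, ip + 1L, rl)
        bases <- paste0(left, right)
        pos <- st + seq_len(rl - 1L) - 1L
        ins_rows[[length(ins_rows) + 1L]] <- data.frame(
          pos = ia$indel_contig_pos[i], allele = ia$indel_allele[i],
          strand = strand, stringsAsFactors = FALSE)
      } else {
        ip <- ia$indel_read_pos[i]
        dp <- ia$indel_contig_pos[i]
        bases <- rseq
        pos <- c(st + seq_len(ip - 1L) - 1L,
                 dp + seq_len(rl - ip + 1L))
        dels[[strand]][dp] <- dels[[strand]][dp] + 1L
      }
      bi <- base_lookup[as.integer(charToRaw(bases))]
      ok <- bi > 0L
      counts[[strand]] <- counts[[strand]] +
        matrix(tabulate((pos[ok] - 1L) * 4L + bi[ok], nbins = 4L * L),
               nrow = 4L)
    }
    ins <- if (length(ins_rows)) {
      d <- do.call(rbind, ins_rows)
      ag <- stats::aggregate(cbind(n = rep(1L, nrow(d))) ~ pos + allele +
                               strand, data = d, FUN = sum)
      w <- stats::reshape(ag, idvar = c("pos", "allele"),
                          timevar = "strand", direction = "wide")
      fwd <- if (is.null(w[["n.+"]])) rep(0L, nrow(w)) else w[["n.+"]]
      rev <- if (is.null(w[["n.-"]])) rep(0L, nrow(w)) else w[["n.-"]]
      data.frame(pos = w$pos, allele = w$allele,
                 fwd = ifelse(is.na(fwd), 0L, fwd),
                 rev = ifelse(is.na(rev), 0L, rev),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(pos = integer(), allele = character(), fwd = integer(),
                 rev = integer(), stringsAsFactors = FALSE)
    }
    rownames(counts[["+"]]) <- rownames(counts[["-"]]) <- DNA_BASES
    out[[cn]] <- list(ref = cs, counts_fwd = counts[["+"]],
                      counts_rev = counts[["-"]], del_fwd = dels[["+"]],
                      del_rev = dels[["-"]], ins = ins, starts = starts)
  }
  structure(out, class = "pileup")
}

#' Pileup columns in tabular form
#'
#' Flattens a [build_pileup()] result into the per-position table used by
#' the text interface: contig, pos, depth, A, C, G, T, ins, del, fwd, rev.
#'
#' @param pile A `pileup` object.
#' @param positions Optional data frame contig/pos to restrict to.
#' @return Data frame, one row per (selected) position.
#' @export
pileup_columns <- function(pile, positions = NULL) {
  rows <- list()
  for (cn in names(pile)) {
    p <- pile[[cn]]
    L <- ncol(p$counts_fwd)
    idx <- if (is.null(positions)) seq_len(L) else
      positions$pos[positions$contig == cn]
    if (length(idx) == 0L) next
    cf <- p$counts_fwd[, idx, drop = FALSE]
    cr <- p$counts_rev[, idx, drop = FALSE]
    tot <- cf + cr
    del <- p$del_fwd[idx] + p$del_rev[idx]
    ins <- vapply(idx, function(i) sum(p$ins$fwd[p$ins$pos == i] +
                                         p$ins$rev[p$ins$pos == i]),
                  integer(1))
    rows[[cn]] <- data.frame(
      contig = cn, pos = idx, depth = as.integer(colSums(tot) + del),
      A = tot[1L, ], C = tot[2L, ], G = tot[3L, ], T = tot[4L, ],
      ins = ins, del = del,
      fwd = as.integer(colSums(cf) + p$del_fwd[idx]),
      rev = as.integer(colSums(cr) + p$del_rev[idx]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
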