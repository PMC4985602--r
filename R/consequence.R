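# Codon-level consequence annotation of sequence differences against gene
# models: coordinate-to-codon arithmetic, ORF discovery, classification into
# silent/missense/nonsense/frameshift/intergenic calls, and truncation
# lengths for premature stops and frameshifts.

#' Construct a gene model
#'
#' A gene model is a protein-coding interval on a contig, 1-based and
#' inclusive at both ends, whose span (including the stop codon) is a
#' multiple of three.
#'
#' @param contig Contig name.
#' @param start,end 1-based inclusive coordinates of the coding span
#'   (start codon through stop codon).
#' @param strand `"+"` or `"-"`.
#' @param name Gene label used in annotation strings.
#' @return A one-row data frame of class `gene_model`.
#' @examples
#' gene_model("Contig 10", 2209, 4041, "+", "APC transporter")
#' @export
gene_model <- function(contig, start, end, strand = "+", name = "gene") {
  start <- as.integer(start)
  end <- as.integer(end)
  if (start > end) stop("gene start ", start, " > end ", end)
  if ((end - start + 1L) %% 3L != 0L) {
    stop("gene span ", end - start + 1L, " nt is not a multiple of 3")
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  out <- data.frame(contig = contig, start = start, end = end,
                    strand = strand, name = name,
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_model", class(out))
  out
}

#' Codon index of a contig position within a gene
#'
#' Maps a 1-based contig coordinate to the 1-based codon index of the gene
#' containing it. On the forward strand the index is
#' `floor((position - start)/3) + 1`; on the reverse strand
#' `floor((end - position)/3) + 1`.
#'
#' @param gene A [gene_model()] row.
#' @param position 1-based contig coordinate(s) inside the gene.
#' @return Integer codon index (vectorized over `position`).
#' @examples
#' g <- gene_model("Contig 10", 2209, 4041)
#' map_position_to_codon(g, 2518)  # 104
#' @export
map_position_to_codon <- function(gene, position) {
  position <- as.integer(position)
  if (any(position < gene$start | position > gene$end)) {
    bad <- position[position < gene$start | position > gene$end]
    stop("position ", paste(bad, collapse = ", "), " outside gene ",
         gene$name, " [", gene$start, ", ", gene$end,
         "]; classify as intergenic instead")
  }
  if (gene$strand == "+") {
    (position - gene$start) %/% 3L + 1L
  } else {
    (gene$end - position) %/% 3L + 1L
  }
}

#' Protein length encoded by a gene model
#'
#' The coding span includes the stop codon, so a gene of `3n` nucleotides
#' encodes `n - 1` residues.
#'
#' @param gene A [gene_model()] row.
#' @return Number of residues.
#' @examples
#' protein_length(gene_model("Contig 10", 2209, 4041))  # 610
#' @export
protein_length <- function(gene) {
  span <- gene$end - gene$start + 1L
  if (span %% 3L != 0L) {
    stop("gene span ", span, " nt is not a multiple of 3")
  }
  span %/% 3L - 1L
}

# Coding sequence of a gene on its own strand.
gene_cds <- function(gene, contigs) {
  s <- substr(contigs[[gene$contig]], gene$start, gene$end)
  if (gene$strand == "-") s <- revcomp(s) else s
}

#' Find open reading frames on both strands
#'
#' Scans all six frames for maximal ORFs: from the first allowed start codon
#' following a stop (or frame begin) through the next stop codon. Shorter
#' in-frame ORFs nested in a reported one are suppressed.
#'
#' @param contigs Named character vector/list of contig sequences.
#' @param min_length Minimum ORF span in nucleotides, including the stop
#'   codon (default 300).
#' @param start_codons Allowed start codons; ATG/GTG/TTG by default, the
#'   common Firmicutes starts.
#' @return Data frame with columns contig, start, end, strand, protein.
#' @export
find_orfs <- function(contigs, min_length = 300L,
                      start_codons = c("ATG", "GTG", "TTG")) {
  if (min_length < 90L) stop("min_length must be >= 90 nt")
  out <- list()
  for (cname in names(contigs)) {
    fwd <- as.character(contigs[[cname]])
    L <- nchar(fwd)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") fwd else revcomp(fwd)
      for (frame in 0:2) {
        n_codons <- (L - frame) %/% 3L
        if (n_codons < 2L) next
        cod <- substring(s, frame + seq(1L, by = 3L, length.out = n_codons),
                         frame + seq(3L, by = 3L, length.out = n_codons))
        stops <- which(cod %in% STOP_CODONS)
        seg_start <- c(1L, stops + 1L)
        seg_stop <- c(stops, n_codons + 1L)  # sentinel for open segment
        for (i in seq_along(seg_start)) {
          if (seg_stop[i] > n_codons) next  # no terminating stop: skip
          idx <- seg_start[i]:seg_stop[i]
          starts_here <- idx[cod[idx] %in% start_codons & idx < seg_stop[i]]
          if (length(starts_here) == 0L) next
          first <- starts_here[1L]
          span <- (seg_stop[i] - first + 1L) * 3L
          if (span < min_length) next
          # coordinates on the scanned strand, then back to forward
          a <- frame + (first - 1L) * 3L + 1L
          b <- frame + seg_stop[i] * 3L
          if (strand == "+") {
            st <- a; en <- b
          } else {
            st <- L - b + 1L; en <- L - a + 1L
          }
          prot <- translate_to_stop(substr(s, a, b))$protein
          out[[length(out) + 1L]] <- data.frame(
            contig = cname, start = st, end = en, strand = strand,
            protein = prot, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      protein = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$contig, res$start, res$end), , drop = FALSE]
}

# Which gene models contain a contig position? Returns row indices.
genes_containing <- function(genes, contig, position) {
  which(genes$contig == contig & genes$start <= position &
          genes$end >= position)
}

#' Classify a difference record against gene models
#'
#' Substitutions inside a gene are classified by translating the reference
#' and alternate codon (silent/missense/nonsense); length-changing variants
#' inside a gene are frameshifts annotated at the codon containing the first
#' inserted/deleted base; positions outside all genes are intergenic, or
#' `downstream_proximal` when within `proximal_window` nt downstream of a
#' gene's 3' end. Records overlapping several genes yield one call per gene,
#' flagged ambiguous.
#'
#' @param record One difference record (one row of a [difference_records()]
#'   table, or a list with contig/position/ref_allele/alt_allele/type).
#' @param genes Data frame of gene models (rows as from [gene_model()]).
#' @param contigs Named contig sequences (may omit contigs that carry only
#'   intergenic records).
#' @param proximal_window Window in nt for the downstream-proximal class.
#' @return Data frame of class `consequence_call` with columns gene, class,
#'   codon_index, ref_codon, alt_codon, ref_residue, alt_residue,
#'   truncation_after, ambiguous, annotation.
#' @export
classify <- function(record, genes, contigs, proximal_window = 50L) {
  contig <- record$contig
  pos <- as.integer(record$position)
  type <- record$type
  hits <- genes_containing(genes, contig, pos)

  empty_call <- function(class, gene = NA_character_) {
    data.frame(gene = gene, class = class, codon_index = NA_integer_,
               ref_codon = NA_character_, alt_codon = NA_character_,
               ref_residue = NA_character_, alt_residue = NA_character_,
               truncation_after = NA_integer_, ambiguous = FALSE,
               annotation = class, stringsAsFactors = FALSE)
  }

  if (length(hits) == 0L) {
    # downstream of a gene end (strand-aware), within the window?
    down <- which(genes$contig == contig &
                    ((genes$strand == "+" & pos > genes$end &
                        pos <= genes$end + proximal_window) |
                       (genes$strand == "-" & pos < genes$start &
                          pos >= genes$start - proximal_window)))
    if (length(down) > 0L) {
      g <- genes[down[1L], ]
      dist <- if (g$strand == "+") pos - g$end else g$start - pos
      call <- empty_call("downstream_proximal", g$name)
      call$annotation <- paste0(dist, " nt downstream of ", g$name)
      return(structure(call, class = c("consequence_call", class(call))))
    }
    call <- empty_call("intergenic")
    call$annotation <- "Intergenic region"
    return(structure(call, class = c("consequence_call", class(call))))
  }

  calls <- lapply(hits, function(i) {
    g <- genes[i, , drop = FALSE]
    codon <- map_position_to_codon(g, pos)
    cds <- gene_cds(g, contigs)
    n_res <- protein_length(g)
    ref_codon <- substr(cds, 3L * codon - 2L, 3L * codon)
    if (type == "substitution") {
      off <- if (g$strand == "+") (pos - g$start) %% 3L else
        (g$end - pos) %% 3L
      base <- record$alt_allele
      if (g$strand == "-") base <- revcomp(base)
      alt_codon <- ref_codon
      substr(alt_codon, off + 1L, off + 1L) <- base
      ref_aa <- unname(Biostrings::GENETIC_CODE[ref_codon])
      alt_aa <- unname(Biostrings::GENETIC_CODE[alt_codon])
      if (alt_codon %in% STOP_CODONS) {
        cls <- "nonsense"; alt_lab <- "stop"
        trunc <- codon - 1L
      } else if (identical(ref_aa, alt_aa)) {
        cls <- "silent"; alt_lab <- alt_aa; trunc <- NA_integer_
      } else {
        cls <- "missense"; alt_lab <- alt_aa; trunc <- NA_integer_
      }
      ann <- paste0(ref_codon, "-", alt_codon, " = ", codon, ref_aa, "-",
                    alt_lab, " in ", g$name)
      data.frame(gene = g$name, class = cls, codon_index = codon,
                 ref_codon = ref_codon, alt_codon = alt_codon,
                 ref_residue = ref_aa,
                 alt_residue = if (cls == "nonsense") "*" else alt_aa,
                 truncation_after = trunc, ambiguous = FALSE,
                 annotation = ann, stringsAsFactors = FALSE)
    } else {
      # 1-bp insertion or deletion inside a gene: frameshift at the codon
      # containing the first inserted/deleted base (the base after the
      # shared anchor base of a left-normalized record)
      event_pos <- pos + 1L
      codon_ev <- map_position_to_codon(
        g, min(max(event_pos, g$start), g$end))
      fs <- frameshift_effect(g, contigs, record)
      ref_codon_ev <- substr(cds, 3L * codon_ev - 2L, 3L * codon_ev)
      ref_aa <- unname(Biostrings::GENETIC_CODE[ref_codon_ev])
      # report alleles codon-style: the reference codon vs the mutated
      # codon slot (4 nt for an insertion, 2 nt for a deletion)
      net <- nchar(record$alt_allele) - nchar(record$ref_allele)
      alt_str <- record$alt_allele
      if (g$strand == "+") {
        cs_full <- as.character(contigs[[g$contig]])
        mut_contig <- paste0(substr(cs_full, 1L, pos - 1L),
                             record$alt_allele,
                             substr(cs_full, pos + nchar(record$ref_allele),
                                    nchar(cs_full)))
        slot <- g$start + 3L * (codon_ev - 1L)
        alt_str <- substr(mut_contig, slot, slot + 2L + net)
      }
      ann <- paste0(ref_codon_ev, "-", alt_str, " = ", codon_ev, ref_aa,
                    "-frameshift in ", g$name)
      data.frame(gene = g$name, class = "frameshift", codon_index = codon_ev,
                 ref_codon = substr(cds, 3L * codon_ev - 2L, 3L * codon_ev),
                 alt_codon = NA_character_, ref_residue = ref_aa,
                 alt_residue = NA_character_,
                 truncation_after = fs$truncation_after, ambiguous = FALSE,
                 annotation = ann, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, calls)
  if (nrow(out) > 1L) out$ambiguous <- TRUE
  structure(out, class = c("consequence_call", class(out)))
}

#' Truncation length caused by a frameshift
#'
#' Applies the indel to the gene's coding sequence and translates from the
#' start codon until the first stop. `truncation_after` is the number of
#' residues in the mutant product before its (premature) stop; the aberrant
#' tail (residues translated in the shifted frame) is reported separately.
#' If a combination of records restores the frame with no intervening stop,
#' the call is flagged `in_frame_restored`. If no stop is reached by the
#' gene end, translation continues into downstream contig sequence; reaching
#' the contig end without a stop sets `runs_off_contig`.
#'
#' @param gene A [gene_model()] row.
#' @param contigs Named contig sequences.
#' @param records One or more indel difference records applied jointly
#'   (data frame rows with position/ref_allele/alt_allele/type).
#' @return List with truncation_after, tail_length, in_frame_restored,
#'   runs_off_contig.
#' @export
frameshift_effect <- function(gene, contigs, records) {
  records <- as.data.frame(records)
  if (any(!records$type %in% c("insertion", "deletion"))) {
    stop("frameshift_effect expects indel records")
  }
  contig_seq <- as.character(contigs[[gene$contig]])
  # apply indels to the contig (descending position so coordinates hold)
  ord <- order(records$position, decreasing = TRUE)
  mut <- contig_seq
  for (i in ord) {
    p <- as.integer(records$position[i])
    ref <- records$ref_allele[i]
    alt <- records$alt_allele[i]
    if (substr(mut, p, p + nchar(ref) - 1L) != ref) {
      stop("ref allele mismatch at ", gene$contig, ":", p)
    }
    mut <- paste0(substr(mut, 1L, p - 1L), alt,
                  substr(mut, p + nchar(ref), nchar(mut)))
  }
  net <- sum(nchar(records$alt_allele) - nchar(records$ref_allele))
  n_ref <- protein_length(gene)
  first_codon <- min(map_position_to_codon(
    gene, pmin(pmax(as.integer(records$position) + 1L, gene$start),
               gene$end)))

  if (gene$strand == "+") {
    tail_seq <- substr(mut, gene$start, nchar(mut))
  } else {
    tail_seq <- revcomp(substr(mut, 1L, gene$end + net))
  }
  tr <- translate_to_stop(tail_seq)

  restored <- net %% 3L == 0L && tr$hit_stop &&
    tr$n_residues == n_ref
  runs_off <- !tr$hit_stop
  list(truncation_after = if (restored) NA_integer_ else tr$n_residues,
       tail_length = if (restored) 0L else
         max(0L, tr$n_residues - (first_codon - 1L)),
       in_frame_restored = restored,
       runs_off_contig = runs_off)
}
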