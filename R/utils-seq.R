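# Low-level sequence helpers shared by all modules. Sequences are plain
# uppercase character strings (ACGT) internally; Biostrings objects appear
# only at file-format boundaries and for reverse-complement/translation.

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (ACGTN).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Split a sequence string into a character vector of single bases.
seq_chars <- function(x) {
  strsplit(x, "", fixed = TRUE)[[1]]
}

# Codon triplets of an in-frame coding sequence.
seq_codons <- function(x) {
  n <- nchar(x)
  if (n %% 3L != 0L) {
    stop("sequence length ", n, " is not a multiple of 3")
  }
  substring(x, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

# Translate one in-frame DNA string to protein using the standard bacterial
# codon table (table 11 coincides with the standard code for elongation).
# Stops become "*"; translation is not truncated at internal stops.
translate_cds <- function(x) {
  codons <- seq_codons(x)
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# Translate from the first codon up to (not including) the first stop.
# Returns list(protein, n_residues, hit_stop).
translate_to_stop <- function(x) {
  n_codons <- nchar(x) %/% 3L
  codons <- substring(x, seq(1L, by = 3L, length.out = n_codons),
                      seq(3L, by = 3L, length.out = n_codons))
  stop_at <- which(codons %in% STOP_CODONS)
  if (length(stop_at) == 0L) {
    aa <- Biostrings::GENETIC_CODE[codons]
    aa[is.na(aa)] <- "X"
    return(list(protein = paste(aa, collapse = ""),
                n_residues = n_codons, hit_stop = FALSE))
  }
  k <- stop_at[1L] - 1L
  aa <- if (k > 0L) Biostrings::GENETIC_CODE[codons[seq_len(k)]] else character()
  aa[is.na(aa)] <- "X"
  list(protein = paste(aa, collapse = ""), n_residues = k, hit_stop = TRUE)
}

# Random DNA string of length n under the current RNG state.
random_dna <- function(n, gc = 0.42) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# Replace the substring of `x` at [start, start+nchar(value)-1] by `value`.
str_overwrite <- function(x, start, value) {
  paste0(substr(x, 1L, start - 1L), value,
         substr(x, start + nchar(value), nchar(x)))
}

# Count mismatching characters between two equal-length strings.
count_mismatches <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  if (length(ra) != length(rb)) {
    stop("count_mismatches: strings differ in length (",
         length(ra), " vs ", length(rb), ")")
  }
  sum(ra != rb)
}

# Left-normalize an indel against the reference sequence, VCF-style: while
# ref and alt end in the same base, drop it and prepend the preceding
# reference base, so the event is reported at its leftmost equivalent
# position with ref and alt sharing their first (anchor) base.
# Returns list(position, ref, alt).
normalize_indel <- function(contig_seq, position, ref, alt) {
  repeat {
    lr <- nchar(ref); la <- nchar(alt)
    if (position > 1L && lr > 0L && la > 0L &&
        substr(ref, lr, lr) == substr(alt, la, la)) {
      ref <- substr(ref, 1L, lr - 1L)
      alt <- substr(alt, 1L, la - 1L)
      if (nchar(ref) == 0L || nchar(alt) == 0L) {
        position <- position - 1L
        anchor <- substr(contig_seq, position, position)
        ref <- paste0(anchor, ref)
        alt <- paste0(anchor, alt)
      }
    } else {
      break
    }
  }
  list(position = position, ref = ref, alt = alt)
}
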