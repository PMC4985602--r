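# Shared fixtures and independent oracles for the test suite.

# Small deterministic genome for mapper/caller tests.
tiny_genome <- function(seed = 5L, total_length = 12000L, n_contigs = 2L,
                        repeats = NULL) {
  build_genome(n_contigs = n_contigs, total_length = total_length,
               gene_density = 0.3, repeat_spec = repeats, seed = seed)
}

# Brute-force alignment oracle: score every start position on every contig
# and both strands, ungapped and with every possible single 1-bp indel.
# Returns the best locus and score (mismatches + 1 per indel).
brute_force_align <- function(read, contigs) {
  best <- list(score = Inf)
  rl <- nchar(read)
  for (cn in names(contigs)) {
    cs <- as.character(contigs[[cn]])
    L <- nchar(cs)
    for (strand in c("+", "-")) {
      r <- if (strand == "+") read else revcomp(read)
      rr <- charToRaw(r)
      for (st in seq_len(max(0L, L - rl + 1L))) {
        mm <- sum(rr != charToRaw(substr(cs, st, st + rl - 1L)))
        if (mm < best$score) {
          best <- list(score = mm, contig = cn, start = st,
                       strand = strand, mismatches = mm, indel = FALSE)
        }
      }
      # single 1-bp indels, only worth checking when they can beat the
      # current best (each costs 1)
      for (st in seq_len(max(0L, L - rl + 2L))) {
        ia <- resistseq:::indel_alignment(r, cs, st)
        if (!is.null(ia) && ia$mismatches + 1L < best$score) {
          best <- list(score = ia$mismatches + 1L, contig = cn,
                       start = st, strand = strand,
                       mismatches = ia$mismatches, indel = TRUE)
        }
      }
    }
  }
  best
}

# Reads sampled error-free from fixed positions of a contig (forward).
exact_reads <- function(contig_seq, starts, rl = 250L) {
  r <- substring(contig_seq, starts, starts + rl - 1L)
  names(r) <- paste0("r", seq_along(r))
  r
}
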