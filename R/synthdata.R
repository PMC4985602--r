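# Synthetic study generator: truth genomes with a designed focal gene,
# mutant strains, paired-end reads, crude-assembly emulation and
# dose-response plates. Every generator is deterministic for a fixed seed
# and emits a truth manifest for recovery scoring.

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# ---------------------------------------------------------------------------
# Focal-protein architecture: a 610-residue APC-transporter-like protein
# with 12 transmembrane helices. Helix intervals are chosen so that
# truncations after residues 103, 190 and 394 fall between helices 2 and 3,
# inside helix 5, and exactly at the end of helix 10, and so that the loop
# between helices 11 and 12 carries residues 425 and 428.

#' Designed 12-helix transmembrane architecture
#'
#' Helix intervals (start/end residues) of the engineered 610-residue
#' membrane protein used throughout the synthetic study.
#'
#' @return Data frame with columns helix, start, end.
#' @export
tm_architecture <- function() {
  data.frame(
    helix = 1:12,
    start = c(20L, 60L, 110L, 140L, 181L, 215L, 250L, 285L, 320L, 375L,
              405L, 435L),
    end   = c(39L, 79L, 129L, 159L, 200L, 234L, 269L, 304L, 339L, 394L,
              424L, 454L))
}

FOCAL_PROTEIN_LENGTH <- 610L

# Residues pinned by the engineered mutation scenario (1-based index -> aa).
focal_pinned_residues <- function() {
  c("1" = "M", "104" = "R", "176" = "G", "177" = "F", "190" = "I",
    "191" = "K", "377" = "A", "387" = "S", "395" = "W", "425" = "M",
    "428" = "H")
}

# Design the focal protein residue-by-residue: hydrophobic cycles inside
# helices, mildly hydrophilic cycles in loops, pinned residues overriding.
focal_protein_residues <- function(pins = focal_pinned_residues()) {
  arch <- tm_architecture()
  helix_cycle <- c("I", "L", "I", "V", "I", "F", "L", "I", "V", "L")
  loop_cycle <- c("N", "S", "D", "T", "G", "Q")
  res <- character(FOCAL_PROTEIN_LENGTH)
  in_helix <- rep(FALSE, FOCAL_PROTEIN_LENGTH)
  for (i in seq_len(nrow(arch))) in_helix[arch$start[i]:arch$end[i]] <- TRUE
  res[in_helix] <- rep_len(helix_cycle, sum(in_helix))
  res[!in_helix] <- rep_len(loop_cycle, sum(!in_helix))
  res[as.integer(names(pins))] <- pins
  res
}

#' Engineered 12-helix test protein
#'
#' The clean (no mutation-site pins) version of the designed membrane
#' protein, together with its designed helix intervals. Used to exercise
#' hydropathy-based helix prediction against known truth.
#'
#' @return List with elements `protein` (character string, 610 aa) and
#'   `helices` (data frame as [tm_architecture()]).
#' @export
make_tm_protein <- function() {
  list(protein = paste(focal_protein_residues(pins = c("1" = "M")),
                       collapse = ""),
       helices = tm_architecture())
}

# Synonymous codons per amino acid (standard code).
codons_by_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

# Build the focal gene nucleotide sequence (1,833 nt: 610 codons + TAA).
# Pinned codons fix the seven mutation sites; codons 178-191 are chosen so
# that after the engineered 1-bp insertion in codon 177 the +1 frame is
# stop-free through codon 190 and stops at codon 191. The sequence is a
# package constant (fixed internal seed).
focal_gene_seq <- function() {
  local_seed(20160505L, {
    res <- focal_protein_residues()
    by_aa <- codons_by_aa()
    # codon 176 ends in A so the codon-177 T-run insertion left-normalizes
    # no further than position 2737 (codon 177)
    pinned_codons <- c("1" = "ATG", "104" = "CGA", "176" = "GGA",
                       "177" = "TTC", "190" = "ATT", "191" = "AAA",
                       "377" = "GCG", "387" = "TCT", "395" = "TGG",
                       "425" = "ATG", "428" = "CAT")
    codons <- character(FOCAL_PROTEIN_LENGTH + 1L)
    # shifted-frame stop constraint applies where the +1 frame after the
    # codon-177 insertion must stay open (codons 178..190)
    constrained <- 178:190
    for (i in seq_len(FOCAL_PROTEIN_LENGTH)) {
      key <- as.character(i)
      if (key %in% names(pinned_codons)) {
        codons[i] <- pinned_codons[[key]]
        next
      }
      cand <- by_aa[[res[i]]]
      if (i %in% constrained) {
        prev_last <- substr(codons[i - 1L], 3L, 3L)
        shifted <- paste0(prev_last, substr(cand, 1L, 2L))
        cand <- cand[!shifted %in% STOP_CODONS]
        if (length(cand) == 0L) {
          stop("no shift-safe codon for residue ", res[i], " at ", i)
        }
      }
      codons[i] <- if (length(cand) == 1L) cand else sample(cand, 1L)
    }
    codons[FOCAL_PROTEIN_LENGTH + 1L] <- "TAA"
    paste(codons, collapse = "")
  })
}

FOCAL_GENE_START <- 2209L
FOCAL_GENE_END <- 4041L
FOCAL_GENE_NAME <- "APC family amino acid-polyamine-organocation transporter"

#' Gene model of the engineered focal gene
#'
#' @param contig Contig name the gene is placed on.
#' @return A [gene_model()] row spanning positions 2209-4041 (+ strand).
#' @export
focal_gene_model <- function(contig = "contig_3") {
  gene_model(contig, FOCAL_GENE_START, FOCAL_GENE_END, "+", FOCAL_GENE_NAME)
}

# ---------------------------------------------------------------------------
# Genome construction

# Sample a free interval of length len on a contig of length L, rejecting
# overlaps with `occupied` (data frame start/end) plus a margin.
sample_free_interval <- function(L, len, occupied, margin = 10L,
                                 tries = 200L) {
  for (i in seq_len(tries)) {
    s <- sample.int(L - len + 1L, 1L)
    e <- s + len - 1L
    if (nrow(occupied) == 0L ||
        all(e + margin < occupied$start | s - margin > occupied$end)) {
      return(c(s, e))
    }
  }
  NULL
}

random_gene_seq <- function(n_codons) {
  by_aa <- codons_by_aa()
  non_stop <- setdiff(names(Biostrings::GENETIC_CODE)[
    !names(Biostrings::GENETIC_CODE) %in% STOP_CODONS], character())
  body <- sample(non_stop, n_codons - 2L, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""),
         sample(STOP_CODONS, 1L))
}

#' Build a synthetic truth genome
#'
#' Generates a multi-contig genome carrying one designed focal gene of
#' exactly 1,833 nt (610-residue product) at positions 2209-4041 of its
#' contig, additional random protein-coding genes at the requested density,
#' and near-identical repeat pairs that later corrupt the emulated assembly
#' consensus. Deterministic for a fixed seed.
#'
#' @param n_contigs Number of contigs (default 5).
#' @param total_length Total genome size in nt (default 50 kb; >= 10 kb).
#' @param gene_density Genes per kb, focal gene included (default 0.6).
#' @param repeat_spec List with `n` (repeat pairs), `length` (nt) and
#'   `identity` (fraction, >= 0.95) or `NULL` for no repeats.
#' @param seed Integer seed.
#' @return An object of class `genome_model`: list with `contigs` (named
#'   character), `genes` (data frame contig/start/end/strand/name/focal),
#'   `repeats` (data frame contig/start/end/src_contig/src_start/src_end),
#'   and `seed`.
#' @export
build_genome <- function(n_contigs = 5L, total_length = 50000L,
                         gene_density = 0.6,
                         repeat_spec = list(n = 2L, length = 800L,
                                            identity = 0.97),
                         seed = 1L) {
  if (total_length < 10000L) stop("total_length must be >= 10 kb")
  if (!is.null(repeat_spec) && repeat_spec$identity < 0.95) {
    stop("repeat identity must be >= 0.95")
  }
  local_seed(seed, {
    lens <- rep(total_length %/% n_contigs, n_contigs)
    lens[n_contigs] <- lens[n_contigs] + total_length %% n_contigs
    cnames <- paste0("contig_", seq_len(n_contigs))
    contigs <- vapply(lens, random_dna, character(1))
    names(contigs) <- cnames

    focal_contig <- cnames[min(3L, n_contigs)]
    if (lens[match(focal_contig, cnames)] < FOCAL_GENE_END + 10L) {
      stop("contig ", focal_contig, " too short (",
           lens[match(focal_contig, cnames)],
           " nt) to host the focal gene ending at ", FOCAL_GENE_END)
    }
    occupied <- lapply(cnames, function(x)
      data.frame(start = integer(), end = integer()))
    names(occupied) <- cnames

    # focal gene + upstream in-frame stop guard so ORF bounds are exact
    contigs[focal_contig] <- str_overwrite(contigs[focal_contig],
                                           FOCAL_GENE_START, focal_gene_seq())
    contigs[focal_contig] <- str_overwrite(contigs[focal_contig],
                                           FOCAL_GENE_START - 3L, "TAA")
    genes <- focal_gene_model(focal_contig)
    genes$focal <- TRUE
    occupied[[focal_contig]] <- data.frame(start = FOCAL_GENE_START - 3L,
                                           end = FOCAL_GENE_END)

    # repeat pairs: copy a source interval elsewhere at >= 95% identity
    repeats <- data.frame(contig = character(), start = integer(),
                          end = integer(), src_contig = character(),
                          src_start = integer(), src_end = integer(),
                          stringsAsFactors = FALSE)
    if (!is.null(repeat_spec) && repeat_spec$n > 0L) {
      for (r in seq_len(repeat_spec$n)) {
        sc <- sample(cnames, 1L)
        src <- sample_free_interval(lens[match(sc, cnames)],
                                    repeat_spec$length, occupied[[sc]])
        if (is.null(src)) next
        occupied[[sc]] <- rbind(occupied[[sc]],
                                data.frame(start = src[1], end = src[2]))
        tc <- sample(cnames, 1L)
        tgt <- sample_free_interval(lens[match(tc, cnames)],
                                    repeat_spec$length, occupied[[tc]])
        if (is.null(tgt)) next
        occupied[[tc]] <- rbind(occupied[[tc]],
                                data.frame(start = tgt[1], end = tgt[2]))
        copy <- substr(contigs[sc], src[1], src[2])
        n_sub <- round((1 - repeat_spec$identity) * repeat_spec$length)
        if (n_sub > 0L) {
          at <- sample.int(repeat_spec$length, n_sub)
          ch <- seq_chars(copy)
          ch[at] <- vapply(ch[at], function(b)
            sample(setdiff(DNA_BASES, b), 1L), character(1))
          copy <- paste(ch, collapse = "")
        }
        contigs[tc] <- str_overwrite(contigs[tc], tgt[1], copy)
        repeats <- rbind(repeats,
                         data.frame(contig = c(sc, tc),
                                    start = c(src[1], tgt[1]),
                                    end = c(src[2], tgt[2]),
                                    src_contig = sc, src_start = src[1],
                                    src_end = src[2],
                                    stringsAsFactors = FALSE))
      }
    }

    # fill remaining gene budget with random genes
    n_target <- round(gene_density * total_length / 1000)
    budget_nt <- sum((n_target - 1L) * 900L)
    if (budget_nt > 0.8 * total_length) {
      stop("gene_density ", gene_density, " genes/kb needs ~", budget_nt,
           " coding nt but the genome has only ", total_length,
           " nt; reduce the density or enlarge the genome")
    }
    made <- 1L
    attempts <- 0L
    while (made < n_target && attempts < 50L * n_target) {
      attempts <- attempts + 1L
      cn <- sample(cnames, 1L)
      n_codons <- sample(100:400, 1L)
      span <- 3L * n_codons
      L <- lens[match(cn, cnames)]
      if (span + 6L >= L) next
      iv <- sample_free_interval(L, span + 6L, occupied[[cn]], margin = 20L)
      if (is.null(iv)) next
      strand <- sample(c("+", "-"), 1L)
      gseq <- random_gene_seq(n_codons)
      gstart <- iv[1] + 3L
      gend <- gstart + span - 1L
      if (strand == "+") {
        contigs[cn] <- str_overwrite(contigs[cn], gstart - 3L,
                                     paste0("TAA", gseq))
      } else {
        contigs[cn] <- str_overwrite(contigs[cn], gstart,
                                     paste0(revcomp(gseq), "TTA"))
      }
      occupied[[cn]] <- rbind(occupied[[cn]],
                              data.frame(start = iv[1], end = iv[2]))
      made <- made + 1L
      g <- gene_model(cn, gstart, gend, strand, paste0("gene_", made))
      g$focal <- FALSE
      genes <- rbind(genes, g)
    }
    genes <- genes[order(genes$contig, genes$start), ]
    rownames(genes) <- NULL
    structure(list(contigs = contigs, genes = genes, repeats = repeats,
                   seed = seed),
              class = "genome_model")
  })
}

#' @export
print.genome_model <- function(x, ...) {
  cat("Synthetic genome:", length(x$contigs), "contigs,",
      sum(nchar(x$contigs)), "nt,", nrow(x$genes), "genes (",
      sum(x$genes$focal), "focal ),", nrow(x$repeats),
      "repeat intervals; seed", x$seed, "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Mutant strains

#' Inject mutations into strain genomes
#'
#' Applies point mutations and 1-bp indels to copies of the truth genome,
#' one copy per strain, and emits a truth manifest for recovery scoring.
#' Indel specs are left-normalized before application so manifest
#' coordinates match the variant caller's reporting convention.
#'
#' @param genome A [build_genome()] result.
#' @param specs Data frame with columns contig, position (1-based),
#'   ref_allele, alt_allele, strains (comma-separated strain labels).
#' @return List with `genomes` (named list: strain -> named contig vector)
#'   and `manifest` (data frame strain/contig/position/ref_allele/
#'   alt_allele/type).
#' @export
inject_mutations <- function(genome, specs) {
  specs <- as.data.frame(specs)
  if (nrow(specs) > 0) {
    # validate and normalize
    for (i in seq_len(nrow(specs))) {
      cs <- genome$contigs[[specs$contig[i]]]
      p <- as.integer(specs$position[i])
      ref <- specs$ref_allele[i]
      alt <- specs$alt_allele[i]
      if (abs(nchar(ref) - nchar(alt)) > 1L) {
        stop("only substitutions and 1-bp indels are supported at ",
             specs$contig[i], ":", p)
      }
      obs <- substr(cs, p, p + nchar(ref) - 1L)
      if (obs != ref) {
        stop("ref allele mismatch at ", specs$contig[i], ":", p,
             ": spec says ", ref, " but genome has ", obs)
      }
      if (ref == alt) stop("ref and alt identical at ", specs$contig[i],
                           ":", p)
      if (nchar(ref) != nchar(alt)) {
        nrm <- normalize_indel(cs, p, ref, alt)
        specs$position[i] <- nrm$position
        specs$ref_allele[i] <- nrm$ref
        specs$alt_allele[i] <- nrm$alt
      }
    }
  }
  specs$type <- ifelse(nchar(specs$ref_allele) == nchar(specs$alt_allele),
                       "substitution",
                       ifelse(nchar(specs$alt_allele) >
                                nchar(specs$ref_allele),
                              "insertion", "deletion"))
  strain_lists <- strsplit(as.character(specs$strains), ",[ ]*")
  strains <- sort(unique(unlist(strain_lists)))
  genomes <- list()
  manifest <- list()
  for (s in strains) {
    mine <- specs[vapply(strain_lists, function(x) s %in% x, logical(1)), ,
                  drop = FALSE]
    gs <- genome$contigs
    ord <- order(mine$position, decreasing = TRUE)
    for (i in ord) {
      cn <- mine$contig[i]
      p <- as.integer(mine$position[i])
      gs[cn] <- paste0(substr(gs[cn], 1L, p - 1L), mine$alt_allele[i],
                       substr(gs[cn], p + nchar(mine$ref_allele[i]),
                              nchar(gs[cn])))
    }
    genomes[[s]] <- gs
    if (nrow(mine) > 0) {
      manifest[[s]] <- data.frame(strain = s, contig = mine$contig,
                                  position = as.integer(mine$position),
                                  ref_allele = mine$ref_allele,
                                  alt_allele = mine$alt_allele,
                                  type = mine$type,
                                  stringsAsFactors = FALSE)
    }
  }
  manifest <- if (length(manifest)) do.call(rbind, manifest) else
    data.frame(strain = character(), contig = character(),
               position = integer(), ref_allele = character(),
               alt_allele = character(), type = character())
  rownames(manifest) <- NULL
  list(genomes = genomes, manifest = manifest)
}

# The seven engineered focal-gene mutation specs, with the strain pattern of
# the study scenario (three strains share the frameshift, two share one of
# the substitutions).
focal_mutation_specs <- function(contig = "contig_3") {
  g0 <- FOCAL_GENE_START - 1L
  data.frame(
    contig = contig,
    position = g0 + c(310L, 529L, 1129L, 1159L, 1185L, 1274L, 1283L),
    ref_allele = c("C", "T", "G", "T", "G", "T", "A"),
    alt_allele = c("T", "TT", "A", "C", "A", "A", "G"),
    strains = c("JK3", "JK4,JK5,JK6", "JK2", "JK1", "JK10", "JK11",
                "JK8,JK9"),
    stringsAsFactors = FALSE)
}

#' Default study mutation scenario
#'
#' The seven focal-gene mutations with the study's strain sharing pattern
#' (a nonsense at codon 104, a 1-bp insertion in codon 177 shared by three
#' strains, substitutions at codons 377/387/395/425/428), plus 0-3 random
#' background substitutions per strain placed in callable regions (outside
#' repeats and any supplied avoid-intervals).
#'
#' @param genome A [build_genome()] result.
#' @param seed Integer seed for background placement.
#' @param n_background_max Maximum background mutations per strain.
#' @param avoid Optional data frame (contig/start/end) of intervals to keep
#'   background mutations out of (e.g. low-coverage assembly segments).
#' @param edge_margin Distance (nt) kept from contig ends; defaults to one
#'   insert length plus one read length. Fully-contained fragment sampling
#'   on a linear contig covers end-proximal positions from one strand only
#'   (real fragments extend past contig junctions), so sites closer to an
#'   end than the insert length cannot show the balanced strand
#'   representation the verification stage checks for.
#' @return Mutation spec data frame for [inject_mutations()].
#' @export
default_mutation_specs <- function(genome, seed = 1L, n_background_max = 3L,
                                   avoid = NULL, edge_margin = 750L) {
  focal_contig <- genome$genes$contig[genome$genes$focal][1]
  specs <- focal_mutation_specs(focal_contig)
  strains <- c("JK1", "JK2", "JK3", "JK4", "JK5", "JK6", "JK8", "JK9",
               "JK10", "JK11")
  margin <- 300L
  blocked <- genome$repeats[, c("contig", "start", "end")]
  blocked <- rbind(blocked,
                   data.frame(contig = focal_contig,
                              start = FOCAL_GENE_START - margin,
                              end = FOCAL_GENE_END + margin))
  if (!is.null(avoid) && nrow(avoid) > 0) {
    blocked <- rbind(blocked, avoid[, c("contig", "start", "end")])
  }
  local_seed(seed + 7L, {
    used <- data.frame(contig = specs$contig, position = specs$position)
    bg <- list()
    for (s in strains) {
      n_bg <- sample(0:n_background_max, 1L)
      for (j in seq_len(n_bg)) {
        for (try in 1:100) {
          cn <- sample(names(genome$contigs), 1L)
          L <- nchar(genome$contigs[[cn]])
          p <- sample.int(L - 2L * edge_margin, 1L) + edge_margin
          bl <- blocked[blocked$contig == cn, , drop = FALSE]
          if (nrow(bl) > 0 &&
              any(p >= bl$start - margin & p <= bl$end + margin)) next
          if (any(used$contig == cn & abs(used$position - p) < 10L)) next
          ref <- substr(genome$contigs[[cn]], p, p)
          alt <- sample(setdiff(DNA_BASES, ref), 1L)
          bg[[length(bg) + 1L]] <- data.frame(
            contig = cn, position = p, ref_allele = ref, alt_allele = alt,
            strains = s, stringsAsFactors = FALSE)
          used <- rbind(used, data.frame(contig = cn, position = p))
          break
        }
      }
    }
    if (length(bg)) specs <- rbind(specs, do.call(rbind, bg))
  })
  specs[order(specs$contig, specs$position), ]
}

# ---------------------------------------------------------------------------
# Read simulation

#' Read-simulation parameters
#'
#' @param read_length Read length in nt (default 250, MiSeq-class).
#' @param mean_coverage Target mean depth (default 50).
#' @param error_rate Per-base substitution error probability (< 0.05).
#' @param insert_mean,insert_sd Fragment-length distribution (nt).
#' @param seed Integer seed.
#' @return A list of class `read_sim_params`.
#' @export
read_sim_params <- function(read_length = 250L, mean_coverage = 50,
                            error_rate = 0.005, insert_mean = 500L,
                            insert_sd = 50L, seed = 1L) {
  if (read_length <= 0L) stop("read_length must be positive")
  if (error_rate < 0 || error_rate >= 0.05) {
    stop("error_rate must be in [0, 0.05)")
  }
  if (mean_coverage <= 0) stop("mean_coverage must be positive")
  structure(list(read_length = as.integer(read_length),
                 mean_coverage = mean_coverage, error_rate = error_rate,
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 seed = seed),
            class = "read_sim_params")
}

#' Simulate paired-end reads from a strain genome
#'
#' Uniform fragment sampling from both strands, fixed-length mates read
#' inward from the fragment ends, and i.i.d. substitution-only sequencing
#' errors. Realized coverage matches the request to within a rounding error;
#' the simulation is deterministic per seed.
#'
#' @param strain_genome Named character vector of contig sequences.
#' @param params A [read_sim_params()] object.
#' @return List of class `read_set` with `r1` and `r2` (named character
#'   vectors; mate ids end in `/1` and `/2`) and `params`.
#' @export
simulate_reads <- function(strain_genome, params = read_sim_params()) {
  rl <- params$read_length
  local_seed(params$seed, {
    r1 <- character(0); r2 <- character(0)
    for (cn in names(strain_genome)) {
      s <- as.character(strain_genome[[cn]])
      L <- nchar(s)
      if (L < rl) next
      n_pairs <- max(1L, round(L * params$mean_coverage / (2 * rl)))
      ins <- pmin(pmax(round(stats::rnorm(n_pairs, params$insert_mean,
                                          params$insert_sd)), rl), L)
      st <- vapply(L - ins + 1L, function(m) sample.int(m, 1L), integer(1))
      frag <- substring(s, st, st + ins - 1L)
      flip <- stats::runif(n_pairs) < 0.5
      frag[flip] <- revcomp(frag[flip])
      a <- substring(frag, 1L, rl)
      b <- revcomp(substring(frag, ins - rl + 1L, ins))
      ids <- paste0(cn, ":", seq_len(n_pairs))
      names(a) <- paste0(ids, "/1")
      names(b) <- paste0(ids, "/2")
      r1 <- c(r1, a); r2 <- c(r2, b)
    }
    # substitution errors
    if (params$error_rate > 0) {
      for (mate in 1:2) {
        reads <- if (mate == 1) r1 else r2
        n <- length(reads)
        n_err <- stats::rbinom(1L, n * rl, params$error_rate)
        if (n_err > 0L) {
          idx <- sample.int(n, n_err, replace = TRUE)
          pos <- sample.int(rl, n_err, replace = TRUE)
          dup <- duplicated(paste(idx, pos))
          idx <- idx[!dup]; pos <- pos[!dup]
          tmp <- reads[idx]
          orig <- substring(tmp, pos, pos)
          shift <- sample.int(3L, length(idx), replace = TRUE)
          newb <- DNA_BASES[(match(orig, DNA_BASES) - 1L + shift) %% 4L + 1L]
          substr(tmp, pos, pos) <- newb
          reads[idx] <- tmp
        }
        if (mate == 1) r1 <- reads else r2 <- reads
      }
    }
    structure(list(r1 = r1, r2 = r2, params = params), class = "read_set")
  })
}

#' @export
print.read_set <- function(x, ...) {
  cat("Paired read set:", length(x$r1), "pairs of",
      x$params$read_length, "nt reads (error rate",
      x$params$error_rate, ")\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Crude-assembly emulation

#' Assembly-emulation parameters
#'
#' @param low_coverage_fraction Fraction of positions placed in the
#'   unreliable 1-5x assembly-coverage band (default 0.03).
#' @param consensus_error_rate_in_low_coverage Per-position probability of a
#'   consensus error inside that band (default 0.01).
#' @param mean_coverage Mean assembly coverage elsewhere (default 50).
#' @param seed Integer seed.
#' @return A list of class `assembly_params`.
#' @export
assembly_params <- function(low_coverage_fraction = 0.03,
                            consensus_error_rate_in_low_coverage = 0.01,
                            mean_coverage = 50, seed = 1L) {
  structure(list(low_coverage_fraction = low_coverage_fraction,
                 consensus_error_rate = consensus_error_rate_in_low_coverage,
                 mean_coverage = mean_coverage, seed = seed),
            class = "assembly_params")
}

#' Emulate a crude draft assembly
#'
#' Produces the draft contigs the pipeline maps against: the truth genome
#' with consensus errors injected only at positions whose emulated assembly
#' coverage falls in the unreliable 1-5x band. Repeat intervals are assigned
#' low coverage (assemblers collapse them), low-coverage segments are placed
#' at random elsewhere, and every injected error is recorded in the truth
#' manifest. A per-position coverage track is returned for the filtering
#' stage.
#'
#' @param genome A [build_genome()] result.
#' @param params An [assembly_params()] object.
#' @param protect Optional data frame (contig/start/end) of intervals kept
#'   out of the low-coverage band (default: the focal gene, mirroring the
#'   study's well-covered target region).
#' @return List of class `crude_assembly`: `contigs` (with consensus
#'   errors), `coverage` (named list of integer vectors), `errors` (data
#'   frame contig/position/truth_base/assembly_base), `params`.
#' @export
emulate_crude_assembly <- function(genome, params = assembly_params(),
                                   protect = NULL) {
  if (is.null(protect)) {
    g <- genome$genes[genome$genes$focal, , drop = FALSE]
    protect <- if (nrow(g)) g[, c("contig", "start", "end")] else
      data.frame(contig = character(), start = integer(), end = integer())
  }
  local_seed(params$seed + 13L, {
    contigs <- genome$contigs
    coverage <- list()
    errors <- list()
    for (cn in names(contigs)) {
      L <- nchar(contigs[[cn]])
      cov <- pmax(6L, round(stats::rnorm(L, params$mean_coverage,
                                         params$mean_coverage / 7)))
      low <- rep(FALSE, L)
      # repeats collapse to low coverage
      rp <- genome$repeats[genome$repeats$contig == cn, , drop = FALSE]
      for (i in seq_len(nrow(rp))) low[rp$start[i]:rp$end[i]] <- TRUE
      # random low-coverage segments up to the requested fraction
      target <- round(params$low_coverage_fraction * L)
      pr <- protect[protect$contig == cn, , drop = FALSE]
      guard <- 0L
      while (sum(low) < target && guard < 1000L) {
        guard <- guard + 1L
        seg <- sample(100:400, 1L)
        s <- sample.int(L - seg, 1L)
        e <- s + seg - 1L
        if (nrow(pr) > 0 && any(e >= pr$start & s <= pr$end)) next
        low[s:e] <- TRUE
      }
      cov[low] <- sample.int(5L, sum(low), replace = TRUE)
      coverage[[cn]] <- cov
      # consensus errors only inside the unreliable band
      cand <- which(cov <= 5L)
      hit <- cand[stats::runif(length(cand)) < params$consensus_error_rate]
      if (length(hit) > 0L) {
        truth <- substring(contigs[[cn]], hit, hit)
        shift <- sample.int(3L, length(hit), replace = TRUE)
        newb <- DNA_BASES[(match(truth, DNA_BASES) - 1L + shift) %% 4L + 1L]
        cs <- contigs[[cn]]
        for (i in seq_along(hit)) {
          substr(cs, hit[i], hit[i]) <- newb[i]
        }
        contigs[[cn]] <- cs
        errors[[cn]] <- data.frame(contig = cn, position = hit,
                                   truth_base = truth, assembly_base = newb,
                                   stringsAsFactors = FALSE)
      }
    }
    errors <- if (length(errors)) do.call(rbind, errors) else
      data.frame(contig = character(), position = integer(),
                 truth_base = character(), assembly_base = character())
    rownames(errors) <- NULL
    structure(list(contigs = contigs, coverage = coverage, errors = errors,
                   params = params),
              class = "crude_assembly")
  })
}

# ---------------------------------------------------------------------------
# Dose-response plates

#' Simulate a two-fold dilution dose-response series
#'
#' Growth follows a sharp Hill-type inhibition curve crossing 50% at the
#' true MIC, read out as endpoint optical density with Gaussian noise.
#'
#' @param true_mic True MIC (nmol/L).
#' @param dilution_steps Number of two-fold dilutions (default 11).
#' @param top_concentration Highest concentration on the plate (nmol/L).
#' @param noise_sd OD noise standard deviation (default 0.02).
#' @param seed Integer seed.
#' @param hill Hill coefficient of the inhibition curve (default 4; the
#'   assay response is close to all-or-none over one dilution step).
#' @param od_max,od_blank Uninhibited-growth and blank OD600 readings.
#' @return A [dilution_series()] object.
#' @export
make_dose_response <- function(true_mic, dilution_steps = 11L,
                               top_concentration = 64 * true_mic,
                               noise_sd = 0.02, seed = 1L, hill = 4,
                               od_max = 1.0, od_blank = 0.05) {
  local_seed(seed, {
    conc <- top_concentration * 2^(-(seq_len(dilution_steps) - 1L))
    inhibition <- 1 / (1 + (true_mic / conc)^hill)
    od <- od_blank + (od_max - od_blank) * (1 - inhibition)
    if (noise_sd > 0) od <- pmax(0, od + stats::rnorm(length(od), 0,
                                                      noise_sd))
    dilution_series(concentrations = conc, od = od, od_blank = od_blank,
                    od_growth = od_max)
  })
}
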