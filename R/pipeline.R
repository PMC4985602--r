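# End-to-end orchestration of the simulated study: generate the truth
# genome and mutant strains, emulate the crude assembly, simulate reads,
# map, call, filter, annotate, localize, assay resistance, and score
# recovery against the truth manifest.

#' Study configuration
#'
#' All per-stage parameter blocks of the simulated study, with the default
#' desk-scale scenario: a 50-kb, 5-contig genome hosting the engineered
#' focal gene, ten mutant strains carrying the seven focal mutations plus
#' random background mutations, 250-nt paired-end reads at 50x with 0.5%
#' substitution errors, a crude assembly with consensus errors confined to
#' its unreliable 1-5x band, and MIC plates at the study's wild-type and
#' mutant resistance scales.
#'
#' @param seed Master seed; stage seeds derive from it.
#' @param genome,reads,assembly Parameter lists/objects for
#'   [build_genome()], [read_sim_params()], [assembly_params()].
#' @param policy A [filter_policy()].
#' @param mic_scenario List with wildtype_mic (nmol/L), fold (true mutant
#'   fold resistance), steps, noise_sd.
#' @param out_dir Optional directory; when set, report TSV/FASTA files are
#'   written there.
#' @return List of class `run_config`.
#' @export
study_config <- function(seed = 1L,
                         genome = list(n_contigs = 5L,
                                       total_length = 50000L,
                                       gene_density = 0.6,
                                       repeat_spec = list(n = 2L,
                                                          length = 800L,
                                                          identity = 0.97)),
                         reads = read_sim_params(seed = seed),
                         assembly = assembly_params(seed = seed),
                         policy = filter_policy(),
                         mic_scenario = list(wildtype_mic = 0.5,
                                             fold = 600, steps = 12L,
                                             noise_sd = 0.02),
                         out_dir = NULL) {
  reads$seed <- seed
  assembly$seed <- seed
  structure(list(seed = seed, genome = genome, reads = reads,
                 assembly = assembly, policy = policy,
                 mic_scenario = mic_scenario, out_dir = out_dir),
            class = "run_config")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f)
  unname(tools::md5sum(f))
}

stage_msg <- function(...) {
  message(format(Sys.time(), "%H:%M:%S"), " [resistseq] ", ...)
}

#' Run the simulated resistance study end to end
#'
#' Executes every stage on synthetic data with known truth: genome and
#' strain generation, crude-assembly emulation, read simulation for the
#' wild type and all ten mutants, mapping, difference calling, merging,
#' the exclusion/verification filters, candidate-gene ranking, codon-level
#' consequence annotation with transmembrane localization, MIC
#' fold-resistance estimation, and a truth-recovery scorecard. Fully
#' deterministic per seed.
#'
#' @param config A [study_config()].
#' @return List of class `study_report`.
#' @export
run_simulated_study <- function(config = study_config()) {
  t0 <- Sys.time()
  stage_msg("building truth genome (seed ", config$seed, ")")
  genome <- do.call(build_genome, c(config$genome,
                                    list(seed = config$seed)))

  stage_msg("emulating crude assembly")
  assembly <- emulate_crude_assembly(genome, config$assembly)

  stage_msg("designing mutant strains")
  low_iv <- coverage_intervals(assembly$coverage,
                               config$policy$low_coverage_max)
  specs <- default_mutation_specs(genome, seed = config$seed,
                                  avoid = low_iv)
  inj <- inject_mutations(genome, specs)
  strain_genomes <- c(list(VT1 = genome$contigs), inj$genomes)

  stage_msg("simulating and mapping reads for ",
            length(strain_genomes), " strains")
  index <- build_index(assembly$contigs)
  per_strain <- list()
  for (s in names(strain_genomes)) {
    rp <- config$reads
    rp$seed <- config$seed + match(s, names(strain_genomes))
    rs <- simulate_reads(strain_genomes[[s]], rp)
    reads <- c(rs$r1, rs$r2)
    aln <- map_reads(reads, index, assembly$contigs)
    pile <- build_pileup(aln, assembly$contigs)
    per_strain[[s]] <- call_differences(pile, assembly$contigs,
                                        coverage_track = assembly$coverage)
    stage_msg("  ", s, ": ", length(reads), " reads, ",
              sum(aln$mapped), " mapped, ",
              nrow(per_strain[[s]]), " raw differences")
  }

  stage_msg("merging and filtering")
  merged <- merge_strains(per_strain)
  filt <- apply_filters(merged, assembly$coverage, config$policy)
  ranking <- rank_candidate_genes(filt$retained, genome$genes)

  stage_msg("annotating consequences")
  consequences <- annotate_records(filt$retained, genome$genes,
                                   genome$contigs)
  topo <- topology_model(tm_architecture())
  consequences$localization <- vapply(seq_len(nrow(consequences)),
                                      function(i) {
    if (is.na(consequences$gene[i]) ||
        consequences$gene[i] != FOCAL_GENE_NAME) {
      return(NA_character_)
    }
    localize_call(consequences[i, ], topo)$descriptor
  }, character(1))

  stage_msg("scoring recovery against the truth manifest")
  scorecard <- score_recovery(filt$retained, inj$manifest,
                              assembly$errors, merged)

  stage_msg("estimating MIC fold resistance")
  mic <- mic_scenario_results(config)

  report <- structure(list(
    config = config, config_hash = config_hash(config), seed = config$seed,
    genome = genome, assembly = assembly, mutation_specs = specs,
    manifest = inj$manifest, merged = merged, filter = filt,
    ranking = ranking, consequences = consequences, topology = topo,
    scorecard = scorecard, mic = mic,
    elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "study_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# Intervals (contig/start/end) where the assembly coverage is at or below
# the unreliable band, for keeping synthetic mutations callable.
coverage_intervals <- function(coverage, low_max) {
  rows <- list()
  for (cn in names(coverage)) {
    r <- rle(coverage[[cn]] <= low_max)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    if (any(keep)) {
      rows[[cn]] <- data.frame(contig = cn, start = starts[keep],
                               end = ends[keep], stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(contig = character(), start = integer(), end = integer())
}

# Classify every retained record, one row per record (primary gene call).
annotate_records <- function(retained, genes, contigs,
                             proximal_window = 50L) {
  if (nrow(retained) == 0L) {
    return(cbind(as.data.frame(retained),
                 data.frame(gene = character(), class = character(),
                            codon_index = integer(),
                            truncation_after = integer(),
                            annotation_call = character())))
  }
  calls <- lapply(seq_len(nrow(retained)), function(i) {
    cc <- classify(retained[i, ], genes, contigs, proximal_window)
    cc[1L, ]
  })
  calls <- do.call(rbind, calls)
  out <- as.data.frame(retained)
  out$gene <- calls$gene
  out$class <- calls$class
  out$codon_index <- calls$codon_index
  out$ref_codon <- calls$ref_codon
  out$alt_codon <- calls$alt_codon
  out$truncation_after <- calls$truncation_after
  out$annotation_call <- calls$annotation
  out
}

# Compare retained records with the injected truth.
score_recovery <- function(retained, manifest, assembly_errors, merged) {
  truth_key <- unique(with(manifest, paste(contig, position, ref_allele,
                                           alt_allele)))
  called_key <- with(retained, paste(contig, position, ref_allele,
                                     alt_allele))
  tp <- sum(truth_key %in% called_key)
  fn_key <- setdiff(truth_key, called_key)
  fp_key <- setdiff(called_key, truth_key)
  err_pos <- paste(assembly_errors$contig, assembly_errors$position)
  merged_key <- with(merged, paste(contig, position))
  artifacts_called <- sum(err_pos %in% merged_key)
  artifacts_retained <- sum(err_pos %in%
                              with(retained, paste(contig, position)))
  list(n_truth = length(truth_key), n_retained = nrow(retained),
       true_positives = tp,
       sensitivity = if (length(truth_key)) tp / length(truth_key) else NA,
       precision = if (nrow(retained)) tp / nrow(retained) else NA,
       missed = fn_key, spurious = fp_key,
       artifacts_injected = length(err_pos),
       artifacts_called = artifacts_called,
       artifacts_retained = artifacts_retained)
}

# The MIC scenario: wild type at its true MIC, one mutant at fold x that,
# each on a ladder reaching 2 steps above its true value, plus replicates.
mic_scenario_results <- function(config) {
  sc <- config$mic_scenario
  wt_true <- sc$wildtype_mic
  mut_true <- sc$wildtype_mic * sc$fold
  reps <- lapply(1:3, function(r) {
    wt <- estimate_mic(make_dose_response(
      wt_true, sc$steps, top_concentration = 4 * wt_true,
      noise_sd = sc$noise_sd, seed = config$seed + 100L * r))
    mut <- estimate_mic(make_dose_response(
      mut_true, sc$steps, top_concentration = 4 * mut_true,
      noise_sd = sc$noise_sd, seed = config$seed + 100L * r + 1L))
    list(wildtype = wt, mutant = mut)
  })
  fold <- fold_increase(reps[[1]]$mutant, reps[[1]]$wildtype,
                        replicates = reps)
  list(wildtype_mic = reps[[1]]$wildtype, mutant_mic = reps[[1]]$mutant,
       fold = fold, true_fold = sc$fold)
}

#' @export
print.study_report <- function(x, ...) {
  cat("Simulated resistance study (seed ", x$seed, ", config ",
      substr(x$config_hash, 1, 8), ")\n", sep = "")
  print(x$genome)
  print(x$filter)
  cat("Top candidate gene:", if (nrow(x$ranking)) x$ranking$gene[1] else
    "none", "\n")
  if (nrow(x$ranking)) {
    cat("  distinct mutated sites:", x$ranking$n_sites[1],
        "| strains hit:", x$ranking$n_strains[1], "\n")
  }
  cat("Recovery: sensitivity", x$scorecard$sensitivity, "precision",
      x$scorecard$precision, "\n")
  cat("MIC fold increase:", signif(x$mic$fold$fold, 2), "(true",
      x$mic$true_fold, ")\n")
  cat("Elapsed:", round(x$elapsed, 1), "s\n")
  invisible(x)
}

# Write the report bundle as reviewable text files.
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(seed = report$seed, config_hash = report$config_hash)
  write_config(meta, file.path(out_dir, "run_metadata.yaml"))
  write_fasta(report$genome$contigs, file.path(out_dir, "truth_genome.fa"))
  write_fasta(report$assembly$contigs,
              file.path(out_dir, "crude_assembly.fa"))
  utils::write.table(report$manifest,
                     file.path(out_dir, "truth_manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_difference_report(report$merged,
                          file.path(out_dir, "differences_raw.tsv"))
  utils::write.table(cbind(as.data.frame(report$filter$excluded)),
                     file.path(out_dir, "differences_excluded.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$consequences,
                     file.path(out_dir, "differences_annotated.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$ranking,
                     file.path(out_dir, "candidate_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' Replay the study's difference-report fixture
#'
#' Runs filtering, consequence annotation and candidate-gene ranking on a
#' difference-report table (by default the packaged 58-record fixture).
#' Annotation strings are regenerated from the engineered focal-gene
#' sequence, not copied from the fixture.
#'
#' @param fixture A [difference_records()] table
#'   (default [make_difference_fixture()]).
#' @param genes Gene models (default [fixture_gene_models()]).
#' @param contigs Contig sequences for annotation
#'   (default [fixture_contigs()]).
#' @param policy A [filter_policy()].
#' @return List of class `fixture_replay`: `filter` ([apply_filters()]
#'   result), `ranking`, `annotated` (retained records with regenerated
#'   consequence calls).
#' @export
replay_fixture <- function(fixture = make_difference_fixture(),
                           genes = fixture_gene_models(),
                           contigs = fixture_contigs(),
                           policy = filter_policy()) {
  filt <- apply_filters(fixture, coverage_track = NULL, policy = policy)
  ranking <- rank_candidate_genes(filt$retained, genes)
  annotated <- annotate_records(filt$retained, genes, contigs)
  structure(list(filter = filt, ranking = ranking, annotated = annotated),
            class = "fixture_replay")
}

#' @export
print.fixture_replay <- function(x, ...) {
  print(x$filter)
  if (nrow(x$ranking)) {
    cat("Top gene:", x$ranking$gene[1], "with", x$ranking$n_sites[1],
        "distinct sites in", x$ranking$n_strains[1], "strains\n")
  }
  invisible(x)
}
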