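# File-format boundaries. Sequences travel as plain character vectors
# inside the package; Biostrings handles FASTA/FASTQ and rtracklayer GFF3.

#' Read contig sequences from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write contig sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write reads to FASTQ (Phred+33, constant quality)
#'
#' @param reads Named character vector of read sequences.
#' @param path Output file.
#' @param quality_char Single quality character (default "I", Q40).
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  qs <- Biostrings::BStringSet(vapply(nchar(reads), function(n)
    strrep(quality_char, n), character(1)))
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads),
    Biostrings::PhredQuality(qs))
  names(x) <- names(reads)
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ file.
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Read gene models from GFF3
#'
#' CDS/gene features become [gene_model()] rows; the `Name` (or `ID`)
#' attribute supplies the label.
#'
#' @param path GFF3 file.
#' @return Gene-model data frame.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type %in% c("gene", "CDS")]
  nm <- if (!is.null(gr$Name)) as.character(gr$Name) else
    as.character(gr$ID)
  nm[is.na(nm)] <- paste0("gene_", which(is.na(nm)))
  out <- do.call(rbind, lapply(seq_along(gr), function(i) {
    gene_model(as.character(GenomicRanges::seqnames(gr)[i]),
               GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i],
               as.character(GenomicRanges::strand(gr)[i]), nm[i])
  }))
  out
}

#' Write gene models to GFF3
#'
#' @param genes Gene-model data frame.
#' @param path Output file.
#' @export
write_gene_models <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig,
    ranges = IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand)
  gr$type <- "gene"
  gr$Name <- genes$name
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write a difference-record table as TSV
#'
#' @param records A [difference_records()] table.
#' @param path Output file.
#' @export
write_difference_report <- function(records, path) {
  utils::write.table(as.data.frame(records), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a difference-record table from TSV
#'
#' @param path TSV written by [write_difference_report()].
#' @return A [difference_records()] table.
#' @export
read_difference_report <- function(path) {
  difference_records(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Read/write generator and policy configuration as YAML
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_config
#' @param config Configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Read a microtiter plate CSV
#'
#' Expected columns: strain, replicate, blank, growth, then one OD column
#' per concentration named `conc_<value>` (nmol/L, descending two-fold).
#'
#' @param path CSV file.
#' @return List of [dilution_series()] keyed by `strain.replicate`.
#' @export
read_plate_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  conc_cols <- grep("^conc_", names(df), value = TRUE)
  conc <- as.numeric(sub("^conc_", "", conc_cols))
  ord <- order(conc, decreasing = TRUE)
  out <- list()
  for (i in seq_len(nrow(df))) {
    key <- paste(df$strain[i], df$replicate[i], sep = ".")
    out[[key]] <- dilution_series(
      concentrations = conc[ord],
      od = as.numeric(df[i, conc_cols[ord]]),
      od_blank = df$blank[i], od_growth = df$growth[i])
  }
  out
}

#' Write dilution series to a plate CSV
#'
#' @param series_list Named list of [dilution_series()] (names
#'   `strain.replicate`).
#' @param path Output file.
#' @export
write_plate_csv <- function(series_list, path) {
  rows <- lapply(names(series_list), function(key) {
    s <- series_list[[key]]
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    row <- data.frame(strain = parts[1],
                      replicate = if (length(parts) > 1) parts[2] else "1",
                      blank = s$od_blank, growth = s$od_growth,
                      stringsAsFactors = FALSE)
    od <- as.data.frame(as.list(s$od))
    names(od) <- paste0("conc_", signif(s$concentrations, 6))
    cbind(row, od)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
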