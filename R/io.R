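#' Read amplicon reads from FASTA or FASTQ
#'
#' Sequence order is preserved; FASTQ qualities are parsed but not used
#' downstream. Gzipped files are read transparently. Malformed records raise
#' a parse error.
#'
#' @param path file path.
#' @param sample_id sample label (default: file name without extension).
#' @return a \code{read_set}.
#' @export
read_fasta <- function(path, sample_id = NULL) {
  read_seqfile(path, "fasta", sample_id)
}

#' @rdname read_fasta
#' @export
read_fastq <- function(path, sample_id = NULL) {
  read_seqfile(path, "fastq", sample_id)
}

read_seqfile <- function(path, format, sample_id) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (is.null(sample_id))
    sample_id <- sub("\\.(fa|fasta|fq|fastq)(\\.gz)?$", "", basename(path))
  if (format == "fastq") validate_fastq(path)
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = format),
    error = function(e) stopf("failed to parse %s as %s: %s", path, format,
                              conditionMessage(e)))
  out <- as.character(seqs)
  names(out) <- sub("\\s.*$", "", names(seqs) %||% paste0("read", seq_along(seqs)))
  structure(list(sequences = out, sample_id = sample_id, truth = NULL),
            class = "read_set")
}

# structural FASTQ check (Biostrings is lenient about truncated records);
# connections auto-detect gzip
validate_fastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  while (length(lines) > 0 && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (length(lines) == 0L) return(invisible(TRUE))
  if (length(lines) %% 4L != 0L)
    stopf("failed to parse %s: truncated FASTQ record near line %d",
          path, length(lines))
  idx <- seq(1L, length(lines), by = 4L)
  bad_hdr <- idx[!startsWith(lines[idx], "@")]
  if (length(bad_hdr) > 0)
    stopf("failed to parse %s: expected '@' header at line %d", path, bad_hdr[1])
  bad_sep <- idx[!startsWith(lines[idx + 2L], "+")]
  if (length(bad_sep) > 0)
    stopf("failed to parse %s: expected '+' separator at line %d",
          path, bad_sep[1] + 2L)
  bad_q <- idx[nchar(lines[idx + 1L]) != nchar(lines[idx + 3L])]
  if (length(bad_q) > 0)
    stopf("failed to parse %s: quality length mismatch at line %d",
          path, bad_q[1] + 3L)
  invisible(TRUE)
}

#' Write a read set to FASTA or FASTQ
#'
#' FASTQ output carries a constant quality (Phred 40, 'I') since the
#' simulator models substitutions, not quality.
#'
#' @param reads a \code{read_set} or named character vector.
#' @param path output file (".gz" suffix compresses).
#' @param format "fasta" or "fastq".
#' @return the path, invisibly.
#' @export
write_reads <- function(reads, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  seqs <- if (inherits(reads, "read_set")) reads$sequences else reads
  x <- Biostrings::DNAStringSet(seqs)
  if (format == "fastq") {
    q <- Biostrings::PhredQuality(strrep("I", nchar(seqs)))
    x <- Biostrings::QualityScaledDNAStringSet(x, q)
    Biostrings::writeQualityScaledXStringSet(x, path, compress = grepl("\\.gz$", path))
  } else {
    Biostrings::writeXStringSet(x, path, compress = grepl("\\.gz$", path))
  }
  invisible(path)
}

#' Write / read a species reference (FASTA + taxonomy TSV)
#'
#' @param reference a \code{reference_set}.
#' @param fasta_path,taxonomy_path output paths (taxonomy columns:
#'   species_id, domain, phylum, family, genus, species).
#' @return the fasta path, invisibly.
#' @export
write_reference <- function(reference, fasta_path, taxonomy_path) {
  stopifnot(inherits(reference, "reference_set"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(reference$templates),
                              fasta_path)
  utils::write.table(reference$taxonomy, taxonomy_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(fasta_path)
}

#' @rdname write_reference
#' @param mustWork error when files are missing.
#' @export
read_reference <- function(fasta_path, taxonomy_path, mustWork = TRUE) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  templates <- as.character(seqs)
  names(templates) <- sub("\\s.*$", "", names(seqs))
  taxonomy <- utils::read.delim(taxonomy_path, stringsAsFactors = FALSE)
  need <- c("species_id", "domain", "phylum", "family", "genus", "species")
  if (!all(need %in% names(taxonomy)))
    stopf("taxonomy table must have columns: %s", paste(need, collapse = ", "))
  if (!setequal(taxonomy$species_id, names(templates)))
    stopf("taxonomy and FASTA species ids disagree")
  structure(list(taxonomy = taxonomy,
                 templates = templates[taxonomy$species_id],
                 amplicon_length = unique(nchar(templates))[1]),
            class = "reference_set")
}
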