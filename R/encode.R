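#' Encode amplicon reads for Hamming-distance clustering
#'
#' Converts a set of nucleotide reads into the fixed-length categorical
#' encoding used by the self-organizing map. Reads shorter than \code{width}
#' are discarded (their number is recorded), longer reads are truncated to
#' \code{width}. Each position is one of A, C, G, T or N; any symbol outside
#' ACGT is mapped to N. The one-hot view of the encoding (one indicator block
#' of width 5 per position, exactly one 1 per block) is available through
#' \code{\link{onehot}}.
#'
#' @param reads a \code{read_set} (see \code{\link{simulate_reads}},
#'   \code{\link{read_fasta}}) or a character vector of sequences, optionally
#'   named by read id.
#' @param width target read length in nucleotides (default 200).
#' @return An object of class \code{encoded_reads}: a list with \code{codes}
#'   (integer matrix, reads x positions, codes 1..5 for A,C,G,T,N),
#'   \code{ids}, \code{width}, and \code{n_discarded}.
#' @examples
#' enc <- encode_reads(c(r1 = "ACGT", r2 = "ACGA"), width = 4)
#' enc$codes
#' @export
encode_reads <- function(reads, width = 200L) {
  seqs <- if (inherits(reads, "read_set")) reads$sequences else reads
  if (!is.character(seqs)) stopf("'reads' must be a read_set or character vector")
  if (length(seqs) == 0L) stopf("empty read set: nothing to encode")
  width <- check_count(width, "width")
  ids <- names(seqs) %||% paste0("read", seq_along(seqs))
  keep <- nchar(seqs) >= width
  n_discarded <- sum(!keep)
  if (!any(keep)) stopf("all %d reads are shorter than %d nt", length(seqs), width)
  codes <- seq_to_codes(seqs[keep], width)
  rownames(codes) <- ids[keep]
  structure(list(codes = codes, ids = ids[keep], width = width,
                 n_discarded = n_discarded),
            class = "encoded_reads")
}

#' One-hot view of encoded reads
#'
#' @param encoded an \code{encoded_reads} object.
#' @param rows which reads to expand (default all).
#' @param nsym alphabet size of the expansion: 4 (ACGT) or 5 (ACGT + N).
#' @return numeric matrix, \code{length(rows)} x \code{width * nsym}; each
#'   per-position block has exactly one 1 (for \code{nsym = 4}, reads
#'   containing N would lose their indicator, so 5 is forced when N occurs).
#' @export
onehot <- function(encoded, rows = seq_len(nrow(encoded$codes)), nsym = NULL) {
  stopifnot(inherits(encoded, "encoded_reads"))
  has_n <- any(encoded$codes[rows, , drop = FALSE] == 5L)
  if (is.null(nsym)) nsym <- if (has_n) 5L else 4L
  if (nsym == 4L && has_n) nsym <- 5L
  out <- codes_to_onehot(encoded$codes, rows, nsym = nsym)
  rownames(out) <- rownames(encoded$codes)[rows]
  out
}

#' @export
print.encoded_reads <- function(x, ...) {
  cat(sprintf("encoded_reads: %d reads x %d nt (%d discarded as too short)\n",
              nrow(x$codes), x$width, x$n_discarded))
  invisible(x)
}

#' Hamming distance between two equal-length sequences
#'
#' Number of positions at which the two sequences carry different symbols.
#'
#' @param a,b character scalars of equal length.
#' @return integer count of differing positions.
#' @examples
#' hamming("ACGT", "ACGA")  # 1
#' @export
hamming <- function(a, b) {
  if (!is.character(a) || !is.character(b) || length(a) != 1L || length(b) != 1L)
    stopf("'a' and 'b' must be single character strings")
  if (nchar(a) != nchar(b))
    stopf("length mismatch: %d vs %d", nchar(a), nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}
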