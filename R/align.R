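#' Optimal local alignment of two nucleotide sequences
#'
#' Smith-Waterman local alignment with affine gaps via
#' \code{Biostrings::pairwiseAlignment}. Scores are given in the usual search
#' convention: positive match reward, negative mismatch and gap scores; a gap
#' of length k contributes \code{gap_open + k * gap_extend}.
#'
#' @param query,target non-empty nucleotide strings.
#' @param match,mismatch substitution scores (defaults +1 / -1).
#' @param gap_open,gap_extend affine gap scores (defaults -2 / -1).
#' @return list with \code{score}, \code{length} (alignment columns including
#'   gaps) and \code{identity} (matches / columns).
#' @examples
#' align_local("ACGT", "TTTT")  # best single-match alignment, score 1
#' @export
align_local <- function(query, target, match = 1, mismatch = -1,
                        gap_open = -2, gap_extend = -1) {
  if (!nzchar(query) || !nzchar(target)) stopf("sequences must be non-empty")
  aln <- Biostrings::pairwiseAlignment(
    pattern = query, subject = target, type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = match, mismatch = mismatch, baseOnly = FALSE),
    gapOpening = -gap_open, gapExtension = -gap_extend)
  cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
  list(score = Biostrings::score(aln), length = cols,
       identity = if (cols > 0) Biostrings::nmatch(aln) / cols else 0)
}

#' Assign clusters to reference species by best local alignment
#'
#' Aligns every cluster representative against every reference template,
#' keeps the best-scoring hit per cluster (ties broken by lexicographically
#' smallest species_id), and drops clusters whose best hit spans fewer than
#' \code{min_alignment_length} alignment columns from downstream counting
#' (the number dropped is recorded in attribute \code{n_dropped}).
#'
#' @param clusters a \code{\link{cluster_reads}} result (or any data.frame
#'   with cluster_id, n_members, representative_id, representative_sequence).
#' @param reference a \code{reference_set}.
#' @param min_alignment_length minimum alignment columns (default 200).
#' @param sample_id sample label attached to the output (defaults to the
#'   clusters' sample id, if any).
#' @param match,mismatch,gap_open,gap_extend see \code{\link{align_local}}.
#' @return data.frame: sample_id, cluster_id, representative_id, species_id,
#'   score, length, identity, n_members, selected (FALSE when filtered out).
#' @export
assign_clusters <- function(clusters, reference, min_alignment_length = 200L,
                            sample_id = NULL, match = 1, mismatch = -1,
                            gap_open = -2, gap_extend = -1) {
  stopifnot(inherits(reference, "reference_set"))
  if (length(reference$templates) == 0L) stopf("empty reference")
  df <- if (inherits(clusters, "read_clusters")) as.data.frame(clusters) else clusters
  if (is.null(sample_id))
    sample_id <- (if (inherits(clusters, "read_clusters")) clusters$sample_id else NULL) %||% "sample"
  reps <- Biostrings::DNAStringSet(df$representative_sequence)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                     mismatch = mismatch,
                                                     baseOnly = FALSE)
  sp_ids <- sort(names(reference$templates))
  n_rep <- length(reps)
  best <- data.frame(species_id = rep(NA_character_, n_rep),
                     score = rep(-Inf, n_rep), length = rep(0L, n_rep),
                     identity = rep(0, n_rep), stringsAsFactors = FALSE)
  for (sp in sp_ids) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = reps, subject = reference$templates[[sp]], type = "local",
      substitutionMatrix = submat,
      gapOpening = -gap_open, gapExtension = -gap_extend)
    sc <- Biostrings::score(aln)
    upd <- sc > best$score          # strict: earlier (smaller) species_id wins ties
    if (any(upd)) {
      cols <- nchar(as.character(Biostrings::alignedPattern(aln[upd])))
      best$species_id[upd] <- sp
      best$score[upd] <- sc[upd]
      best$length[upd] <- cols
      best$identity[upd] <- Biostrings::nmatch(aln[upd]) / cols
    }
  }
  out <- data.frame(sample_id = sample_id, cluster_id = df$cluster_id,
                    representative_id = df$representative_id,
                    species_id = best$species_id, score = best$score,
                    length = best$length, identity = best$identity,
                    n_members = df$n_members,
                    selected = best$length >= min_alignment_length,
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- sum(!out$selected)
  out
}

#' Per-sample species frequency table from assigned clusters
#'
#' For each species, its per-sample frequency is the ratio of the summed
#' sizes of its clusters to the summed sizes of all selected
#' (filter-passing) clusters of the sample; clusters of the same species
#' merge their counts. Rows sum to 1 per sample.
#'
#' @param hits one or more \code{\link{assign_clusters}} results (a single
#'   data.frame, possibly covering several samples).
#' @return long data.frame of class \code{species_frequency_table}:
#'   sample_id, species_id, count, frequency; attribute \code{totals} holds
#'   the per-sample selected-sequence counts.
#' @export
build_frequency_table <- function(hits) {
  stopifnot(is.data.frame(hits))
  empty <- setdiff(unique(hits$sample_id), unique(hits$sample_id[hits$selected]))
  if (length(empty) > 0)
    stopf("empty sample(s) after the alignment filter: %s",
          paste(empty, collapse = ", "))
  sel <- hits[hits$selected, , drop = FALSE]
  agg <- stats::aggregate(n_members ~ sample_id + species_id, data = sel, FUN = sum)
  names(agg)[names(agg) == "n_members"] <- "count"
  totals <- tapply(agg$count, agg$sample_id, sum)
  agg$frequency <- agg$count / as.vector(totals[agg$sample_id])
  agg <- agg[order(agg$sample_id, agg$species_id), , drop = FALSE]
  rownames(agg) <- NULL
  attr(agg, "totals") <- totals
  class(agg) <- c("species_frequency_table", "data.frame")
  agg
}

#' Wide sample-by-species frequency matrix
#'
#' @param freq a \code{\link{build_frequency_table}} result (or any long
#'   data.frame with sample_id, species_id, frequency).
#' @param species optional full species universe for zero-filled columns
#'   (character vector or a \code{reference_set}).
#' @return numeric matrix samples x species; absent species have frequency 0.
#' @export
freq_matrix <- function(freq, species = NULL) {
  if (inherits(species, "reference_set")) species <- names(species$templates)
  sp <- sort(unique(c(freq$species_id, species)))
  sa <- sort(unique(freq$sample_id))
  m <- matrix(0, nrow = length(sa), ncol = length(sp),
              dimnames = list(sa, sp))
  m[cbind(match(freq$sample_id, sa), match(freq$species_id, sp))] <- freq$frequency
  m
}
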