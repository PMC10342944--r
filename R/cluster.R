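#' Cluster cohesion: mean pairwise Pearson correlation of member reads
#'
#' Cohesion of a read cluster is the average Pearson correlation between the
#' one-hot encodings of all member pairs. For one-hot vectors over an alphabet
#' of size a, the pairwise correlation has the exact closed form
#' r = 1 - (a/(a-1)) * h/L with h the Hamming distance between the two reads,
#' which is what this function computes (the alphabet is ACGT, extended by N
#' only when N occurs among the members; two fully divergent ACGT reads give
#' r = -1/3). If the number of member pairs exceeds \code{max_pairs}, a seeded
#' uniform sample of \code{max_pairs} pairs is averaged instead. A singleton
#' cluster has cohesion 1 by convention.
#'
#' @param members integer vector of read row indices into \code{encoded}.
#' @param encoded an \code{\link{encode_reads}} object.
#' @param max_pairs maximum number of pairs evaluated exactly (default 10000).
#' @param seed seed for the pair subsample.
#' @return cohesion R in [-1/(a-1), 1].
#' @export
cluster_cohesion <- function(members, encoded, max_pairs = 10000L, seed = 1L) {
  stopifnot(inherits(encoded, "encoded_reads"))
  n <- length(members)
  if (n < 1L) stopf("cluster has no members")
  if (n == 1L) return(1.0)
  a <- if (any(encoded$codes[members, , drop = FALSE] == 5L)) 5L else 4L
  L <- encoded$width
  n_pairs <- n * (n - 1) / 2
  if (n_pairs <= max_pairs) {
    pr <- utils::combn(n, 2L)
    ai <- members[pr[1L, ]]; bi <- members[pr[2L, ]]
  } else {
    set.seed(seed)
    ai <- integer(0); bi <- integer(0)
    while (length(ai) < max_pairs) {
      x <- sample.int(n, 2L * max_pairs, replace = TRUE)
      y <- sample.int(n, 2L * max_pairs, replace = TRUE)
      ok <- x != y
      ai <- c(ai, members[x[ok]]); bi <- c(bi, members[y[ok]])
    }
    ai <- ai[seq_len(max_pairs)]; bi <- bi[seq_len(max_pairs)]
  }
  h <- C_hamming_pairs(encoded$codes, ai, bi)
  1 - (a / (a - 1)) * mean(h) / L
}

#' Representative read of a cluster
#'
#' The member whose one-hot encoding has maximal Pearson correlation with the
#' cluster's mean one-hot profile; ties go to the smallest read id.
#'
#' @param members integer vector of read row indices into \code{encoded}.
#' @param encoded an \code{\link{encode_reads}} object.
#' @return the representative's read id (character scalar).
#' @export
select_representative <- function(members, encoded) {
  stopifnot(inherits(encoded, "encoded_reads"))
  if (length(members) < 1L) stopf("cluster has no members")
  ids <- rownames(encoded$codes)[members]
  if (length(members) == 1L) return(ids)
  oh <- onehot(encoded, members)
  profile <- colMeans(oh)
  r <- if (stats::sd(profile) == 0) {
    rep(0, length(members))
  } else {
    apply(oh, 1L, function(x) stats::cor(x, profile))
  }
  ids[order(-r, ids)[1L]]
}

compute_cohesion <- function(clusters, encoded, max_pairs = 10000L, seed = 1L) {
  vapply(seq_along(clusters$members), function(k) {
    cluster_cohesion(clusters$members[[k]], encoded, max_pairs,
                     child_seed(seed, k))
  }, numeric(1)) |> stats::setNames(names(clusters$members))
}

#' Subcluster loose SOM clusters
#'
#' Clusters whose cohesion falls below \code{threshold} are re-clustered with
#' a fresh SOM on their own members (default 10 x 10 grid); the resulting
#' subclusters replace the parent. Subclustering is applied exactly once (no
#' recursion). Clusters at or above the threshold pass through unchanged.
#'
#' @param clusters a \code{read_clusters} object with cohesion values (as
#'   produced inside \code{\link{cluster_reads}}, or by filling
#'   \code{clusters$cohesion} from \code{\link{cluster_cohesion}}).
#' @param encoded the \code{encoded_reads} the clusters refer to.
#' @param threshold cohesion threshold (default 0.95).
#' @param subgrid subclustering grid (default 10 x 10).
#' @param rounds training rounds for each subclustering SOM.
#' @param max_pairs,seed see \code{\link{cluster_cohesion}}.
#' @return a \code{read_clusters} object; the read partition is preserved.
#' @export
subcluster_loose <- function(clusters, encoded, threshold = 0.95,
                             subgrid = c(10L, 10L), rounds = 10000L,
                             max_pairs = 10000L, seed = 1L) {
  stopifnot(inherits(clusters, "read_clusters"))
  if (is.null(clusters$cohesion))
    clusters$cohesion <- compute_cohesion(clusters, encoded, max_pairs, seed)
  loose <- names(clusters$members)[clusters$cohesion < threshold &
                                     lengths(clusters$members) > 1L]
  if (length(loose) == 0L) return(clusters)

  members <- clusters$members
  cohesion <- clusters$cohesion
  node <- clusters$node
  subflag <- clusters$subcluster
  for (k in seq_along(loose)) {
    id <- loose[k]
    m <- members[[id]]
    sub_enc <- structure(list(codes = encoded$codes[m, , drop = FALSE],
                              ids = rownames(encoded$codes)[m],
                              width = encoded$width, n_discarded = 0L),
                         class = "encoded_reads")
    fit <- train_som(sub_enc, grid = subgrid, rounds = rounds,
                     seed = child_seed(seed, k))
    sub <- assign_to_nodes(sub_enc, fit)
    sub_ids <- paste0(id, ".s", sub("^n", "", names(sub$members)))
    new_members <- lapply(sub$members, function(loc) m[loc])
    names(new_members) <- sub_ids
    new_coh <- vapply(seq_along(new_members), function(j) {
      cluster_cohesion(new_members[[j]], encoded, max_pairs,
                       child_seed(seed, 1000L + j))
    }, numeric(1))
    pos <- match(id, names(members))
    members <- append(members[-pos], new_members, after = pos - 1L)
    cohesion <- c(cohesion[names(cohesion) != id],
                  stats::setNames(new_coh, sub_ids))
    node <- c(node[names(node) != id],
              stats::setNames(rep(clusters$node[[id]], length(sub_ids)), sub_ids))
    subflag <- c(subflag[names(subflag) != id],
                 stats::setNames(rep(TRUE, length(sub_ids)), sub_ids))
  }
  clusters$members <- members
  clusters$cohesion <- cohesion[names(members)]
  clusters$node <- node[names(members)]
  clusters$subcluster <- subflag[names(members)]
  clusters$representative <- NULL
  clusters
}

#' Cluster a sample's reads with a cohesion-checked self-organizing map
#'
#' End-to-end per-sample clustering: encode reads at fixed length, train a
#' SOM (default 20 x 20 grid, 10000 rounds), map every read to its
#' best-matching node, compute each cluster's cohesion (mean pairwise Pearson
#' correlation of one-hot encodings), subcluster clusters with cohesion below
#' the threshold in a smaller SOM (default 10 x 10), and select the
#' representative read closest to each final cluster's average.
#'
#' @param reads a \code{read_set} or named character vector of sequences.
#' @param width fixed read length (default 200 nt); shorter reads are
#'   discarded, longer ones truncated.
#' @param grid,rounds,mode SOM geometry and schedule, see
#'   \code{\link{train_som}}.
#' @param cohesion_threshold clusters below this cohesion are subclustered
#'   (default 0.95).
#' @param subgrid,subrounds geometry/rounds of the subclustering SOM.
#' @param max_pairs pair budget per cohesion computation.
#' @param seed master seed; all stage seeds derive from it.
#' @return an object of class \code{read_clusters} whose summary table
#'   (\code{as.data.frame}) has one row per final cluster: cluster_id, node,
#'   n_members, cohesion, subcluster flag, representative_id and
#'   representative_sequence. The clusters partition the encoded reads.
#' @examples
#' set.seed(1)
#' reads <- c(rep("ACGTACGTAC", 5), rep("TGCATGCATG", 5))
#' names(reads) <- paste0("r", 1:10)
#' cl <- cluster_reads(reads, width = 10, grid = c(3, 3), rounds = 300,
#'                     subrounds = 300)
#' as.data.frame(cl)
#' @export
cluster_reads <- function(reads, width = 200L, grid = c(20L, 20L),
                          rounds = 10000L, cohesion_threshold = 0.95,
                          subgrid = c(10L, 10L), subrounds = rounds,
                          max_pairs = 10000L, seed = 1L,
                          mode = c("presentations", "epochs")) {
  mode <- match.arg(mode)
  encoded <- encode_reads(reads, width)
  fit <- train_som(encoded, grid = grid, rounds = rounds, seed = seed,
                   mode = mode)
  cl <- assign_to_nodes(encoded, fit)
  cl$cohesion <- compute_cohesion(cl, encoded, max_pairs, seed)
  cl <- subcluster_loose(cl, encoded, threshold = cohesion_threshold,
                         subgrid = subgrid, rounds = subrounds,
                         max_pairs = max_pairs, seed = child_seed(seed, 17L))
  cl$representative <- vapply(cl$members, select_representative,
                              character(1), encoded = encoded)
  seqs <- codes_to_seq(encoded$codes)
  names(seqs) <- rownames(encoded$codes)
  cl$representative_sequence <- seqs[cl$representative]
  names(cl$representative_sequence) <- names(cl$members)
  cl$sample_id <- if (inherits(reads, "read_set")) reads$sample_id else NULL
  cl$n_discarded <- encoded$n_discarded
  cl$codebook <- fit
  cl$encoded <- encoded
  cl
}

#' @method as.data.frame read_clusters
#' @export
as.data.frame.read_clusters <- function(x, ...) {
  data.frame(cluster_id = names(x$members),
             node = unname(x$node[names(x$members)]),
             n_members = unname(lengths(x$members)),
             cohesion = if (is.null(x$cohesion)) NA_real_ else
               unname(x$cohesion[names(x$members)]),
             subcluster = unname(x$subcluster[names(x$members)]),
             representative_id = if (is.null(x$representative)) NA_character_ else
               unname(x$representative[names(x$members)]),
             representative_sequence = if (is.null(x$representative_sequence))
               NA_character_ else unname(x$representative_sequence[names(x$members)]),
             stringsAsFactors = FALSE)
}

#' @export
print.read_clusters <- function(x, ...) {
  cat(sprintf("read_clusters: %d clusters over %d reads (%d subclustered)\n",
              length(x$members), sum(lengths(x$members)), sum(x$subcluster)))
  if (!is.null(x$cohesion))
    cat(sprintf("cohesion: min %.3f / median %.3f\n",
                min(x$cohesion), stats::median(x$cohesion)))
  invisible(x)
}

#' @method summary read_clusters
#' @export
summary.read_clusters <- function(object, ...) {
  df <- as.data.frame(object)
  cat(sprintf("%d clusters, sizes %d..%d (median %.0f)\n", nrow(df),
              min(df$n_members), max(df$n_members), stats::median(df$n_members)))
  if (!all(is.na(df$cohesion)))
    print(summary(df$cohesion))
  invisible(df)
}
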