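# Independent oracles used to cross-check package computations. These are
# deliberately naive implementations (enumeration / dynamic programming /
# direct formula on one-hot vectors) kept separate from the package code.

# Smith-Waterman with affine gaps, O(n*m) DP over three states.
# Scores follow the package convention: a gap of length k scores
# gap_open + k * gap_extend (both negative).
oracle_local_align_score <- function(a, b, match = 1, mismatch = -1,
                                     gap_open = -2, gap_extend = -1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)        # match/mismatch state
  X <- matrix(NEG, n + 1, m + 1)      # gap in b (deletion from a)
  Y <- matrix(NEG, n + 1, m + 1)      # gap in a
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (A[i] == B[j]) match else mismatch
      M[i + 1, j + 1] <- max(0, M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] + gap_open + gap_extend,
                             X[i, j + 1] + gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] + gap_open + gap_extend,
                             Y[i + 1, j] + gap_extend)
      best <- max(best, M[i + 1, j + 1], X[i + 1, j + 1], Y[i + 1, j + 1])
    }
  }
  best
}

# Exact one-sided Wilcoxon signed-rank p-value by enumerating all 2^n sign
# assignments of the ranked absolute differences.
oracle_wilcoxon_exact <- function(d, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  W_all <- as.matrix(signs) %*% r
  if (alternative == "greater") mean(W_all >= W_obs) else mean(W_all <= W_obs)
}

# Nearest-template read assignment (the clustering oracle) and cluster purity
# of a partition against it.
oracle_nearest_template <- function(codes, reference) {
  tc <- amplisom:::seq_to_codes(reference$templates,
                                reference$amplicon_length)
  rownames(tc) <- names(reference$templates)
  apply(codes, 1L, function(x) rownames(tc)[which.min(colSums(t(tc) != x))])
}

oracle_purity <- function(members_list, labels) {
  hit <- vapply(members_list, function(m) max(table(labels[m])), numeric(1))
  sum(hit) / length(labels)
}

# Pearson correlation of two reads' one-hot encodings, computed literally
# with cor() over the expanded vectors.
oracle_onehot_cor <- function(s1, s2, alphabet = c("A", "C", "G", "T")) {
  expand <- function(s) {
    ch <- strsplit(s, "")[[1]]
    as.vector(vapply(ch, function(x) as.numeric(alphabet == x),
                     numeric(length(alphabet))))
  }
  stats::cor(expand(s1), expand(s2))
}

# small deterministic read set helper
make_reads <- function(seqs, prefix = "r") {
  names(seqs) <- sprintf("%s%03d", prefix, seq_along(seqs))
  seqs
}

mutate_seq <- function(s, positions, bases) {
  ch <- strsplit(s, "")[[1]]
  ch[positions] <- bases
  paste0(ch, collapse = "")
}
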