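test_that("cohesion matches the literal one-hot Pearson correlation", {
  # identical members
  enc <- encode_reads(make_reads(rep("ACGTACGTAC", 4)), width = 10)
  expect_equal(cluster_cohesion(1:4, enc), 1.0)

  # fully divergent pair over the 4-letter alphabet: r = -1/3
  enc2 <- encode_reads(make_reads(c("ACGTACGTAC", "CAACCAACCA")), width = 10)
  expect_equal(cluster_cohesion(1:2, enc2), -1/3)
  expect_equal(oracle_onehot_cor("ACGTACGTAC", "CAACCAACCA"), -1/3)

  # singleton convention
  expect_equal(cluster_cohesion(2, enc2), 1.0)

  # random sequence pairs: closed form equals cor() on the one-hot vectors
  set.seed(42)
  for (i in 1:10) {
    s1 <- paste0(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = "")
    s2 <- paste0(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = "")
    e <- encode_reads(make_reads(c(s1, s2)), width = 30)
    expect_equal(cluster_cohesion(1:2, e), oracle_onehot_cor(s1, s2),
                 tolerance = 1e-12)
  }

  # mean over >2 members equals the mean of the pairwise oracle values
  set.seed(43)
  seqs <- vapply(1:5, function(i)
    paste0(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = ""),
    character(1))
  e5 <- encode_reads(make_reads(seqs), width = 20)
  pairs <- utils::combn(5, 2)
  manual <- mean(apply(pairs, 2, function(p) oracle_onehot_cor(seqs[p[1]], seqs[p[2]])))
  expect_equal(cluster_cohesion(1:5, e5), manual, tolerance = 1e-12)
})

test_that("pair subsampling approximates the full cohesion and is seeded", {
  ref <- generate_reference(2, 100, 0.1, seed = 3)
  f <- stats::setNames(c(0.5, 0.5), names(ref$templates))
  rs <- simulate_reads(f, ref, depth = 250, substitution_rate = 0.01, seed = 4)
  enc <- encode_reads(rs$sequences, width = 100)
  full <- cluster_cohesion(1:250, enc, max_pairs = 40000)    # all 31125 pairs
  sub1 <- cluster_cohesion(1:250, enc, max_pairs = 5000, seed = 9)
  sub2 <- cluster_cohesion(1:250, enc, max_pairs = 5000, seed = 9)
  expect_identical(sub1, sub2)
  expect_equal(sub1, full, tolerance = 0.02)
})

test_that("representative selection maximises correlation with the cluster mean", {
  # 9 template copies and one 5-error read: a template copy is representative
  tmpl <- strrep("ACGT", 10)
  noisy <- mutate_seq(tmpl, c(1, 9, 17, 25, 33), c("T", "C", "A", "G", "C"))
  enc <- encode_reads(make_reads(c(rep(tmpl, 9), noisy)), width = 40)
  rep_id <- select_representative(1:10, enc)
  expect_true(rep_id %in% sprintf("r%03d", 1:9))
  expect_equal(rep_id, "r001")   # ties among identical copies -> smallest id

  # singleton is its own representative
  expect_equal(select_representative(10, enc), "r010")
})

test_that("subclustering splits mixed clusters and preserves the partition", {
  ref <- generate_reference(2, 200, 0.5, seed = 21)
  f <- stats::setNames(c(0.5, 0.5), names(ref$templates))
  rs <- simulate_reads(f, ref, depth = 150, substitution_rate = 0.005, seed = 22)
  enc <- encode_reads(rs$sequences, width = 200)
  # degenerate 1x1 parent grid: everything lands in one mixed cluster
  fit <- train_som(enc, grid = c(1, 1), rounds = 200, seed = 23)
  cl <- assign_to_nodes(enc, fit)
  cl$cohesion <- stats::setNames(
    vapply(cl$members, cluster_cohesion, numeric(1), encoded = enc),
    names(cl$members))
  expect_lt(cl$cohesion[[1]], 0.95)

  out <- subcluster_loose(cl, enc, threshold = 0.95, subgrid = c(3, 3),
                          rounds = 2000, seed = 24)
  expect_gt(length(out$members), 1)
  expect_true(all(out$subcluster))
  expect_equal(sort(unname(unlist(out$members))), seq_len(150))   # partition preserved

  truth <- oracle_nearest_template(enc$codes, ref)
  expect_gte(oracle_purity(out$members, truth), 0.95)

  # tight clusters pass through untouched
  tight <- assign_to_nodes(enc, train_som(enc, grid = c(2, 2), rounds = 2000,
                                          seed = 25))
  tight$cohesion <- stats::setNames(
    vapply(tight$members, cluster_cohesion, numeric(1), encoded = enc),
    names(tight$members))
  if (all(tight$cohesion >= 0.95)) {
    expect_identical(subcluster_loose(tight, enc, threshold = 0.95),
                     tight)
  }
})

test_that("cluster_reads is deterministic end to end and partitions reads", {
  ref <- generate_reference(4, 120, 0.2, seed = 31, eukaryote_fraction = 0)
  f <- stats::setNames(rep(0.25, 4), names(ref$templates))
  rs <- simulate_reads(f, ref, depth = 200, substitution_rate = 0.005, seed = 32)
  cl1 <- cluster_reads(rs, width = 120, grid = c(5, 5), rounds = 3000,
                       subrounds = 2000, seed = 33)
  cl2 <- cluster_reads(rs, width = 120, grid = c(5, 5), rounds = 3000,
                       subrounds = 2000, seed = 33)
  expect_identical(as.data.frame(cl1), as.data.frame(cl2))
  expect_equal(sort(unname(unlist(cl1$members))), 1:200)
  df <- as.data.frame(cl1)
  expect_true(all(df$representative_id %in% names(rs$sequences)))
  # representative sequence is the representative read's sequence
  expect_equal(unname(df$representative_sequence),
               unname(rs$sequences[df$representative_id]))
})
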