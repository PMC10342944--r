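toy_db <- function() {
  data.frame(
    species_id = rep(c("spA", "spB"), each = 3),
    pathway_id = rep(c("pw1", "pw2", "pw3"), 2),
    score = c(0.8, 0.1, 0.5, 0.2, 0.9, 0.5),
    h1 = rep(c("biosynthesis", "biosynthesis", "energy"), 2),
    h2 = rep(c("amino-acid biosynthesis", "cofactor biosynthesis",
               "respiration"), 2),
    stringsAsFactors = FALSE)
}

test_that("pathway scores are frequency-weighted sums with linearity", {
  db <- toy_db()
  m <- matrix(c(0.5, 0.5,
                1.0, 0.0,
                0.25, 0.75), nrow = 3, byrow = TRUE,
              dimnames = list(c("s_mix", "s_pure", "s_q"), c("spA", "spB")))
  ps <- sample_pathway_scores(m, db)
  expect_equal(ps["s_mix", "pw1"], 0.5 * 0.8 + 0.5 * 0.2)   # = 0.5
  # single species at frequency 1 -> its score vector verbatim
  expect_equal(unname(ps["s_pure", c("pw1", "pw2", "pw3")]), c(0.8, 0.1, 0.5))
  # linearity: a 50/50 mix of two samples is the mean of their score vectors
  mix <- (m["s_pure", ] + m["s_q", ]) / 2
  ps_mix <- sample_pathway_scores(rbind(mixed = mix), db)
  expect_equal(unname(ps_mix["mixed", ]),
               unname((ps["s_pure", ] + ps["s_q", ]) / 2))

  # species missing from the DB contribute 0, coverage is reported
  m2 <- cbind(m, spGhost = c(0.2, 0, 0))
  m2 <- m2 / rowSums(m2)
  ps2 <- sample_pathway_scores(m2, db)
  expect_equal(unname(attr(ps2, "coverage")["s_mix"]), 1 - 0.2 / 1.2)
  # no overlap at all -> all-zero scores
  ps0 <- sample_pathway_scores(matrix(1, 1, 1, dimnames = list("s", "spNone")), db)
  expect_true(all(ps0 == 0))
})

test_that("hierarchy rollups conserve totals", {
  db <- toy_db()
  m <- matrix(c(0.3, 0.7), nrow = 1,
              dimnames = list("s1", c("spA", "spB")))
  ps <- sample_pathway_scores(m, db)
  h1 <- rollup_hierarchy(ps, "H1")
  h2 <- rollup_hierarchy(ps, "H2")
  expect_equal(h1["s1", "biosynthesis"], ps["s1", "pw1"] + ps["s1", "pw2"])
  expect_equal(unname(rowSums(h1)), unname(rowSums(unclass(ps))))
  expect_equal(unname(rowSums(h2)), unname(rowSums(unclass(ps))))
})

test_that("group shift summary flags injected increases, not stationary data", {
  set.seed(11)
  donors <- sprintf("d%02d", 1:12)
  design <- data.frame(sample_id = c(paste0(donors, "_T0"), paste0(donors, "_T3")),
                       donor_id = rep(donors, 2),
                       group = rep(rep(c("RA", "MetS"), each = 6), 2),
                       timepoint = rep(c("T0", "T3"), each = 12))
  base <- matrix(stats::rnorm(24 * 2, mean = 5, sd = 0.5), nrow = 24,
                 dimnames = list(design$sample_id, c("catA", "catB")))
  # uniform increase injected into catA at T3
  shifted <- base
  shifted[design$timepoint == "T3", "catA"] <-
    shifted[design$timepoint == "T3", "catA"] + 2
  res <- group_shift_summary(shifted, design)
  expect_true(all(res$flagged[res$category == "catA"]))
  expect_true(all(res$p[res$category == "catA"] < 0.05))
  # stationary category stays unflagged in at least most runs of this seed
  expect_false(any(res$flagged[res$category == "catB"]))
  # mean difference equals difference of means
  ra_a <- res[res$group == "RA" & res$category == "catA", ]
  i0 <- design$group == "RA" & design$timepoint == "T0"
  i1 <- design$group == "RA" & design$timepoint == "T3"
  expect_equal(ra_a$mean_t1 - ra_a$mean_t0,
               mean(shifted[i1, "catA"]) - mean(shifted[i0, "catA"]))
})

test_that("species change profiles sort by delta and recover the phylum pattern", {
  ref <- generate_reference(20, 200, 0.1, seed = 61)
  design <- cohort_design(8, 4, seed = 62)
  comp <- generate_composition(design, ref, seed = 63,
                               effect_config = list(n_rare_species = 0L))
  db <- generate_pathway_db(ref, n_pathways = 40, seed = 64, bias = 0.8)
  m <- do.call(rbind, comp$frequencies)
  rownames(m) <- names(comp$frequencies)
  prof <- species_change_profile(m, comp$samples, db, taxonomy = ref)
  # sorted by decreasing delta
  expect_true(all(diff(prof$delta) <= 0))
  # species absent from both timepoints are not reported
  expect_true(all(prof$delta != 0))
  # increasing Bacteroidetes carry higher summed biosynthesis scores than
  # decreasing Firmicutes
  up_bact <- prof$category_score[prof$phylum == "Bacteroidetes" & prof$delta > 0]
  down_firm <- prof$category_score[prof$phylum == "Firmicutes" & prof$delta < 0]
  expect_gt(mean(up_bact), mean(down_firm))
})

test_that("generated cohorts show the post-fasting biosynthesis increase in both groups", {
  ref <- generate_reference(20, 200, 0.1, seed = 71)
  design <- cohort_design(8, 4, seed = 72)
  comp <- generate_composition(design, ref, seed = 73)
  db <- generate_pathway_db(ref, n_pathways = 40, seed = 74)
  m <- do.call(rbind, comp$frequencies)
  rownames(m) <- names(comp$frequencies)
  h1 <- rollup_hierarchy(sample_pathway_scores(m, db), "H1")
  res <- group_shift_summary(h1, comp$samples, categories = "biosynthesis")
  expect_true(all(res$mean_t1 > res$mean_t0))
})
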