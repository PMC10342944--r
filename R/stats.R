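#' Correct population fractions to cells per blood volume
#'
#' Absolute population counts are the leukocyte fraction times the actual
#' leukocyte blood count at sampling.
#'
#' @param fractions population fractions of leukocytes (vector or matrix).
#' @param leukocyte_count leukocyte blood count in cells/nL (scalar, or one
#'   value per row when \code{fractions} is a matrix).
#' @return absolute counts in cells/nL, same shape as \code{fractions}.
#' @export
per_volume_correction <- function(fractions, leukocyte_count) {
  if (any(fractions < 0)) stopf("fractions must be non-negative")
  if (any(leukocyte_count <= 0)) stopf("leukocyte_count must be positive")
  fractions * leukocyte_count
}

#' One-sided paired t-test for kinetics
#'
#' Paired t on donor-matched before/after values; the alternative is that
#' values increase (after > before) or decrease. Pairs with a missing value
#' are dropped.
#'
#' @param before,after equal-length paired vectors (n >= 2 after dropping
#'   missing pairs).
#' @param direction "increase" (default) or "decrease".
#' @return list with \code{t}, \code{df} (n - 1) and one-sided \code{p}.
#' @examples
#' paired_t_one_sided(c(0, 0, 0), c(1, 2, 3))$p  # ~0.0371
#' @export
paired_t_one_sided <- function(before, after,
                               direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  if (length(before) != length(after)) stopf("'before' and 'after' must be paired")
  ok <- stats::complete.cases(before, after)
  before <- before[ok]; after <- after[ok]
  n <- length(before)
  if (n < 2L) stopf("need at least 2 complete pairs (got %d)", n)
  d <- after - before
  if (stats::sd(d) == 0)
    stopf("degenerate input: all paired differences are identical")
  tt <- stats::t.test(after, before, paired = TRUE,
                      alternative = if (direction == "increase") "greater" else "less")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

#' Welch's t-test for unpaired group comparisons
#'
#' Two-sample t-test with the Welch-Satterthwaite degrees of freedom
#' (unequal variances).
#'
#' @param a,b the two samples.
#' @param sides 2 (default) for a two-sided test, 1 for one-sided (alternative
#'   mean(a) > mean(b)).
#' @return list with \code{t}, \code{df} and \code{p}.
#' @examples
#' welch_test(c(1, 2, 3, 4), c(3, 4, 5, 6))  # t = -2.191, df = 6
#' @export
welch_test <- function(a, b, sides = 2L) {
  if (length(a) < 2L || length(b) < 2L) stopf("need at least 2 values per group")
  alt <- if (sides == 2L) "two.sided" else "greater"
  tt <- stats::t.test(a, b, var.equal = FALSE, alternative = alt)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped; the p-value is exact (full enumeration of
#' sign assignments, via the signed-rank distribution) for n <= 25 without
#' ties among the absolute differences, and a normal approximation with
#' continuity correction otherwise.
#'
#' @param before,after equal-length paired vectors.
#' @param sides 1 (default, one-sided in the given direction) or 2.
#' @param direction for one-sided tests: "increase" (after > before, default)
#'   or "decrease".
#' @return list with \code{W} (signed-rank statistic of after vs before),
#'   \code{p}, \code{n} (non-zero pairs) and \code{exact} (logical).
#' @examples
#' wilcoxon_signed_rank(c(0, 0, 0), c(1, 2, 3))$p  # 0.125 = 1/2^3
#' @export
wilcoxon_signed_rank <- function(before, after, sides = 1L,
                                 direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  if (length(before) != length(after)) stopf("'before' and 'after' must be paired")
  ok <- stats::complete.cases(before, after)
  d <- after[ok] - before[ok]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stopf("all paired differences are zero: test undefined")
  ties <- anyDuplicated(abs(d)) > 0
  exact <- n <= 25L && !ties
  alt <- if (sides == 2L) "two.sided"
         else if (direction == "increase") "greater" else "less"
  wt <- suppressWarnings(stats::wilcox.test(d, alternative = alt,
                                            exact = exact, correct = TRUE))
  list(W = unname(wt$statistic), p = unname(wt$p.value), n = n, exact = exact)
}

#' Per-population significance profile and combined score
#'
#' For every cytometric population, computes the three comparisons used to
#' profile a two-group longitudinal cohort: a one-sided paired t-test within
#' the case group between baseline and each of two follow-up timepoints, and
#' Welch's test between the two groups at baseline. The combined score of a
#' population is its weakest (largest) p-value across the three comparisons,
#' so only populations consistently significant in all three rank highly;
#' populations are ranked by ascending combined score. -log10 transforms and
#' per-test significance flags at \code{alpha} are included. Donors missing
#' a timepoint are dropped from the affected pairing.
#'
#' @param x a \code{population_table} (see
#'   \code{\link{generate_cytometry_table}}), or a samples x populations
#'   fraction matrix together with \code{design}.
#' @param design sample metadata (sample_id, donor_id, group, timepoint,
#'   leukocyte_count); taken from \code{x} when it is a population_table.
#' @param paired_group group tested longitudinally (default "RA").
#' @param reference_group comparison group at baseline (default "MetS").
#' @param t0,t1,t2 the baseline and two follow-up timepoints.
#' @param direction direction of the paired alternatives (default "increase").
#' @param value "fraction" (default) or "absolute" (cells/nL via
#'   \code{\link{per_volume_correction}}).
#' @param alpha per-test significance level (default 0.05).
#' @param adjust "none" (default, raw p-values as profiled) or "BH".
#' @return data.frame sorted by ascending combined score: population_id, the
#'   three p-values, their -log10 transforms, per-test significance flags,
#'   combined score, and rank.
#' @export
significance_profile <- function(x, design = NULL, paired_group = "RA",
                                 reference_group = "MetS",
                                 t0 = "T0", t1 = "T1", t2 = "T2",
                                 direction = c("increase", "decrease"),
                                 value = c("fraction", "absolute"),
                                 alpha = 0.05, adjust = c("none", "BH")) {
  direction <- match.arg(direction)
  value <- match.arg(value)
  adjust <- match.arg(adjust)
  if (inherits(x, "population_table")) {
    design <- x$samples
    m <- x$fractions
  } else m <- x
  stopifnot(is.matrix(m), is.data.frame(design))
  design <- design[match(rownames(m), design$sample_id), , drop = FALSE]
  if (value == "absolute")
    m <- per_volume_correction(m, design$leukocyte_count)

  paired_p <- function(pop, tp) {
    i0 <- design$group == paired_group & design$timepoint == t0
    i1 <- design$group == paired_group & design$timepoint == tp
    d0 <- stats::setNames(m[i0, pop], design$donor_id[i0])
    d1 <- stats::setNames(m[i1, pop], design$donor_id[i1])
    donors <- intersect(names(d0), names(d1))
    paired_t_one_sided(d0[donors], d1[donors], direction = direction)$p
  }
  welch_p <- function(pop) {
    ia <- design$group == paired_group & design$timepoint == t0
    ib <- design$group == reference_group & design$timepoint == t0
    welch_test(m[ia, pop], m[ib, pop])$p
  }
  pops <- colnames(m)
  p1 <- vapply(pops, paired_p, numeric(1), tp = t1)
  p2 <- vapply(pops, paired_p, numeric(1), tp = t2)
  p3 <- vapply(pops, welch_p, numeric(1))
  if (adjust == "BH") {
    p1 <- stats::p.adjust(p1, "BH"); p2 <- stats::p.adjust(p2, "BH")
    p3 <- stats::p.adjust(p3, "BH")
  }
  combined <- pmax(p1, p2, p3)
  out <- data.frame(population_id = pops,
                    p_paired_t1 = unname(p1), p_paired_t2 = unname(p2),
                    p_welch_t0 = unname(p3),
                    neglog10_t1 = -log10(unname(p1)),
                    neglog10_t2 = -log10(unname(p2)),
                    neglog10_welch = -log10(unname(p3)),
                    sig_t1 = unname(p1) < alpha, sig_t2 = unname(p2) < alpha,
                    sig_welch = unname(p3) < alpha,
                    combined = unname(combined),
                    stringsAsFactors = FALSE)
  out <- out[order(out$combined, out$population_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
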