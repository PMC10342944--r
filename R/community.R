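#' Simpson's index of diversity
#'
#' D = 1 - sum(p_i^2): the probability that two randomly selected sequences
#' of a sample belong to different species.
#'
#' @param p numeric frequency vector summing to 1 (tolerance 1e-6).
#' @return D in [0, 1).
#' @examples
#' simpson_diversity(c(0.5, 0.3, 0.2))  # 0.62
#' @export
simpson_diversity <- function(p) {
  if (!is.numeric(p) || length(p) == 0L || any(p < 0))
    stopf("'p' must be a non-negative numeric vector")
  if (abs(sum(p) - 1) > 1e-6)
    stopf("frequencies must sum to 1 (got %.8f)", sum(p))
  1 - sum(p^2)
}

#' Species richness of a sample
#'
#' @param p frequency (or count) vector; species with value > 0 are counted.
#' @return integer number of present species.
#' @export
richness <- function(p) {
  if (length(p) == 0L) return(0L)
  sum(p > 0)
}

#' Roll a species frequency table up to a higher taxonomic rank
#'
#' Frequencies are summed within each value of the requested rank; per-sample
#' row sums are preserved.
#'
#' @param m samples x species frequency matrix (see \code{\link{freq_matrix}}).
#' @param taxonomy taxonomy data.frame (species_id plus rank columns) or a
#'   \code{reference_set}.
#' @param rank one of "phylum", "family", "genus", "species".
#' @return samples x rank-values frequency matrix.
#' @export
rollup_taxonomy <- function(m, taxonomy, rank = c("phylum", "family", "genus",
                                                  "species")) {
  rank <- match.arg(rank)
  if (inherits(taxonomy, "reference_set")) taxonomy <- taxonomy$taxonomy
  if (rank == "species") return(m)
  lab <- taxonomy[[rank]][match(colnames(m), taxonomy$species_id)]
  if (anyNA(lab))
    stopf("species missing from taxonomy: %s",
          paste(utils::head(colnames(m)[is.na(lab)], 5), collapse = ", "))
  t(rowsum(t(m), group = lab))
}

#' Species specific to one group at a timepoint
#'
#' Selects species detected (frequency > 0) in at least one sample of the
#' target group/timepoint while absent (frequency exactly 0) from every
#' sample of the excluded group at the excluded timepoints, and tabulates how
#' many target donors carry each selected species.
#'
#' @param m samples x species frequency matrix.
#' @param design sample metadata: data.frame with sample_id, donor_id, group,
#'   timepoint (e.g. the \code{samples} element of a composition set).
#' @param target_group,target_time group/timepoint defining candidates
#'   (defaults RA at T0).
#' @param excluded_group,excluded_times group/timepoints that must be free of
#'   the species (defaults MetS at T0 and T3).
#' @return list with \code{species} (selected ids), \code{carriers} (named
#'   integer: distinct target donors carrying each species) and
#'   \code{histogram} (table: number of species carried by exactly k donors).
#' @export
group_specific_species <- function(m, design, target_group = "RA",
                                   target_time = "T0",
                                   excluded_group = "MetS",
                                   excluded_times = c("T0", "T3")) {
  stopifnot(is.data.frame(design))
  design <- design[match(rownames(m), design$sample_id), , drop = FALSE]
  if (anyNA(design$sample_id)) stopf("design does not cover all samples")
  tgt <- design$group == target_group & design$timepoint == target_time
  exc <- design$group == excluded_group & design$timepoint %in% excluded_times
  if (!any(tgt) || !any(exc))
    stopf("missing group: need samples for %s at %s and %s at {%s}",
          target_group, target_time, excluded_group,
          paste(excluded_times, collapse = ","))
  present_tgt <- colSums(m[tgt, , drop = FALSE] > 0) > 0
  absent_exc <- colSums(m[exc, , drop = FALSE] > 0) == 0
  species <- colnames(m)[present_tgt & absent_exc]
  carriers <- vapply(species, function(sp) {
    length(unique(design$donor_id[tgt & m[, sp] > 0]))
  }, integer(1))
  list(species = species, carriers = carriers,
       histogram = if (length(carriers)) table(carriers) else table(integer(0)))
}

#' Screen species frequencies for correlation with BMI
#'
#' Pearson correlation of per-donor species frequency against donor BMI at
#' one timepoint; species with |R| above the threshold are flagged. Species
#' with zero frequency variance have undefined correlation and are reported
#' as R = 0, never flagged.
#'
#' @param m samples x species frequency matrix.
#' @param design sample metadata with sample_id, donor_id, timepoint and BMI.
#' @param timepoint timepoint screened (default "T0").
#' @param threshold |R| threshold (default 0.4).
#' @return data.frame: species_id, R, flagged.
#' @export
bmi_correlation_screen <- function(m, design, timepoint = "T0",
                                   threshold = 0.4) {
  design <- design[match(rownames(m), design$sample_id), , drop = FALSE]
  sel <- which(design$timepoint == timepoint)
  if (length(sel) < 3L) stopf("need at least 3 donors at %s", timepoint)
  bmi <- design$BMI[sel]
  if (is.null(bmi)) stopf("design lacks a BMI column")
  R <- apply(m[sel, , drop = FALSE], 2L, function(x) {
    if (stats::sd(x) == 0 || stats::sd(bmi) == 0) 0 else stats::cor(x, bmi)
  })
  data.frame(species_id = colnames(m), R = unname(R),
             flagged = unname(abs(R) > threshold), stringsAsFactors = FALSE)
}

#' Per-donor summed frequencies of a species set
#'
#' For each donor, sums the frequencies of the given (e.g. differential
#' eukaryote) species across that donor's samples at the requested
#' timepoints. The result feeds a downstream group comparison such as
#' \code{\link{welch_test}}.
#'
#' @param m samples x species frequency matrix.
#' @param design sample metadata with sample_id, donor_id, timepoint.
#' @param species species_id set to sum over.
#' @param timepoints timepoints combined per donor (default T0 and T3).
#' @return named numeric vector, one value per donor appearing at those
#'   timepoints (0 when none of the species occur).
#' @export
donor_eukaryote_score <- function(m, design, species,
                                  timepoints = c("T0", "T3")) {
  design <- design[match(rownames(m), design$sample_id), , drop = FALSE]
  keep <- design$timepoint %in% timepoints
  species <- intersect(species, colnames(m))
  donors <- unique(design$donor_id[keep])
  out <- vapply(donors, function(d) {
    rows <- which(keep & design$donor_id == d)
    if (length(species) == 0L) 0 else sum(m[rows, species, drop = FALSE])
  }, numeric(1))
  stats::setNames(out, donors)
}

#' Species with suggestive group differences (Welch screen)
#'
#' Per species, Welch's t-test of per-donor mean frequency between the two
#' groups; species with p below the threshold are returned. Used to pick the
#' differential species set for \code{\link{donor_eukaryote_score}}.
#'
#' @param m samples x species frequency matrix.
#' @param design sample metadata with sample_id, donor_id, group.
#' @param alpha screening threshold on the Welch p-value (default 0.1).
#' @param groups the two groups compared (default RA vs MetS).
#' @return data.frame: species_id, p; only rows with p < alpha.
#' @export
differential_species <- function(m, design, alpha = 0.1,
                                 groups = c("RA", "MetS")) {
  design <- design[match(rownames(m), design$sample_id), , drop = FALSE]
  donor_mean <- rowsum(m, group = design$donor_id) /
    as.vector(table(design$donor_id)[sort(unique(design$donor_id))])
  dgrp <- design$group[match(rownames(donor_mean), design$donor_id)]
  p <- apply(donor_mean, 2L, function(x) {
    a <- x[dgrp == groups[1]]; b <- x[dgrp == groups[2]]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) return(1)
    tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1)
  })
  out <- data.frame(species_id = colnames(m), p = unname(p),
                    stringsAsFactors = FALSE)
  out[out$p < alpha, , drop = FALSE]
}
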