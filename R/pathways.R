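#' Frequency-weighted per-sample pathway scores
#'
#' For every sample and pathway, multiplies each species' pathway score by the
#' species' frequency in the sample and sums over species:
#' PS(sample, pathway) = sum_s freq(sample, s) * score(s, pathway). Species
#' absent from the database contribute 0; the fraction of each sample's
#' frequency mass covered by the database is recorded in attribute
#' \code{coverage}.
#'
#' @param m samples x species frequency matrix (see \code{\link{freq_matrix}})
#'   or a long \code{species_frequency_table}.
#' @param db pathway database data.frame: species_id, pathway_id, score
#'   (in [0, 1]), h1, h2 (see \code{\link{generate_pathway_db}}).
#' @return samples x pathways numeric matrix of class \code{pathway_scores}
#'   with attributes \code{hierarchy} (pathway_id, h1, h2) and
#'   \code{coverage}.
#' @export
sample_pathway_scores <- function(m, db) {
  if (inherits(m, "species_frequency_table") ||
      (is.data.frame(m) && all(c("sample_id", "species_id", "frequency") %in% names(m))))
    m <- freq_matrix(m)
  stopifnot(is.matrix(m), is.data.frame(db))
  pw <- sort(unique(db$pathway_id))
  sp_db <- sort(unique(db$species_id))
  S <- matrix(0, nrow = length(sp_db), ncol = length(pw),
              dimnames = list(sp_db, pw))
  S[cbind(match(db$species_id, sp_db), match(db$pathway_id, pw))] <- db$score
  common <- intersect(colnames(m), sp_db)
  ps <- m[, common, drop = FALSE] %*% S[common, , drop = FALSE]
  hier <- unique(db[, c("pathway_id", "h1", "h2")])
  hier <- hier[order(hier$pathway_id), , drop = FALSE]
  structure(ps,
            hierarchy = hier,
            coverage = rowSums(m[, common, drop = FALSE]),
            class = c("pathway_scores", class(ps)))
}

#' Roll pathway scores up the annotation hierarchy
#'
#' Category score = sum of its member pathways' scores per sample; the total
#' over categories equals the total over pathways.
#'
#' @param ps a \code{\link{sample_pathway_scores}} matrix.
#' @param level "H1" or "H2".
#' @param db optional database supplying the hierarchy when \code{ps} lacks
#'   the attribute.
#' @return samples x categories numeric matrix.
#' @export
rollup_hierarchy <- function(ps, level = c("H1", "H2"), db = NULL) {
  level <- match.arg(level)
  hier <- attr(ps, "hierarchy")
  if (is.null(hier)) {
    if (is.null(db)) stopf("no hierarchy available; pass 'db'")
    hier <- unique(db[, c("pathway_id", "h1", "h2")])
  }
  col <- if (level == "H1") "h1" else "h2"
  lab <- hier[[col]][match(colnames(ps), hier$pathway_id)]
  t(rowsum(t(unclass(ps)), group = lab))
}

#' Group-level pathway category shift between two timepoints
#'
#' Per group and category: mean scores at the two timepoints and a one-sided
#' paired t-test on donor-matched values (donors missing either timepoint are
#' dropped). Categories whose p-value is below \code{alpha} are flagged.
#'
#' @param scores samples x categories matrix (a hierarchy rollup or raw
#'   pathway scores).
#' @param design sample metadata: sample_id, donor_id, group, timepoint.
#' @param categories which columns to test (default all).
#' @param t0,t1 timepoints compared (defaults T0 vs T3).
#' @param direction tested alternative, "increase" (t1 > t0, default) or
#'   "decrease".
#' @param alpha significance level for the flag (default 0.05).
#' @return data.frame: group, category, mean_t0, mean_t1, p, flagged.
#' @export
group_shift_summary <- function(scores, design, categories = colnames(scores),
                                t0 = "T0", t1 = "T3",
                                direction = c("increase", "decrease"),
                                alpha = 0.05) {
  direction <- match.arg(direction)
  design <- design[match(rownames(scores), design$sample_id), , drop = FALSE]
  out <- list()
  for (grp in unique(design$group)) {
    for (cat in categories) {
      i0 <- design$group == grp & design$timepoint == t0
      i1 <- design$group == grp & design$timepoint == t1
      d0 <- stats::setNames(scores[i0, cat], design$donor_id[i0])
      d1 <- stats::setNames(scores[i1, cat], design$donor_id[i1])
      donors <- intersect(names(d0), names(d1))
      tt <- paired_t_one_sided(d0[donors], d1[donors], direction = direction)
      out[[length(out) + 1L]] <- data.frame(
        group = grp, category = cat,
        mean_t0 = mean(d0[donors]), mean_t1 = mean(d1[donors]),
        n = length(donors), p = tt$p, flagged = tt$p < alpha,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Per-species abundance change versus summed category score
#'
#' For each species: the change in mean frequency between two timepoints
#' (mean over the group's donors at t1 minus at t0) and the species' summed
#' database score over all pathways of one H1 category. The output is sorted
#' by decreasing frequency change (species_id breaks ties), mirroring the
#' display of species ordered by their mean shift after an intervention.
#'
#' @param m samples x species frequency matrix.
#' @param design sample metadata: sample_id, donor_id, group, timepoint.
#' @param db pathway database (species_id, pathway_id, score, h1, h2).
#' @param h1 H1 category whose scores are summed (default "biosynthesis").
#' @param group cohort group analysed (default "RA").
#' @param t0,t1 timepoints (defaults T0, T3).
#' @param min_delta minimum |change| for a species to be reported (default 0,
#'   i.e. all species with nonzero change).
#' @param taxonomy optional taxonomy (or \code{reference_set}) to attach each
#'   species' phylum.
#' @return data.frame: species_id, delta, category_score (and phylum when
#'   taxonomy is given), sorted by decreasing delta.
#' @export
species_change_profile <- function(m, design, db, h1 = "biosynthesis",
                                   group = "RA", t0 = "T0", t1 = "T3",
                                   min_delta = 0, taxonomy = NULL) {
  design <- design[match(rownames(m), design$sample_id), , drop = FALSE]
  i0 <- design$group == group & design$timepoint == t0
  i1 <- design$group == group & design$timepoint == t1
  delta <- colMeans(m[i1, , drop = FALSE]) - colMeans(m[i0, , drop = FALSE])
  sub <- db[db$h1 == h1, , drop = FALSE]
  score <- tapply(sub$score, sub$species_id, sum)
  out <- data.frame(species_id = colnames(m), delta = unname(delta),
                    category_score = unname(score[colnames(m)]),
                    stringsAsFactors = FALSE)
  out$category_score[is.na(out$category_score)] <- 0
  if (!is.null(taxonomy)) {
    if (inherits(taxonomy, "reference_set")) taxonomy <- taxonomy$taxonomy
    out$phylum <- taxonomy$phylum[match(out$species_id, taxonomy$species_id)]
  }
  out <- out[abs(out$delta) > min_delta | (min_delta == 0 & out$delta != 0), ,
             drop = FALSE]
  out <- out[order(-out$delta, out$species_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
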