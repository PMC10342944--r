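PATHWAY_H2 <- list(
  biosynthesis = c("amino-acid biosynthesis", "cofactor biosynthesis",
                   "nucleotide biosynthesis", "lipid biosynthesis"),
  degradation = c("carbohydrate degradation", "protein degradation"),
  energy = c("respiration", "fermentation"),
  other = c("miscellaneous")
)

#' Generate a synthetic species-by-pathway score database
#'
#' Emulates an export of per-species metabolic pathway presence scores with a
#' two-level annotation hierarchy (H1 in biosynthesis/degradation/energy/other,
#' H2 subcategories). Scores lie in [0, 1]. A configurable phylum bias makes
#' Bacteroidetes and Proteobacteria species carry systematically higher
#' biosynthesis scores and Firmicutes/Actinobacteria lower ones (so the
#' post-fasting "generalist" shift is recoverable from data generated with
#' the default abundance multipliers); with \code{bias = 0} scores are
#' independent of phylum. Only prokaryote species are annotated, as pathway
#' databases of this kind cover bacteria.
#'
#' @param reference a \code{\link{generate_reference}} object.
#' @param n_pathways number of pathways (>= 1, default 40).
#' @param seed integer seed.
#' @param bias non-negative phylum bias strength (default 0.6).
#' @param up_phyla,down_phyla phyla biased towards high / low biosynthesis
#'   scores.
#' @return data.frame (class \code{pathway_db}): species_id, pathway_id,
#'   score, h1, h2.
#' @export
generate_pathway_db <- function(reference, n_pathways = 40L, seed = 1L,
                                bias = 0.6,
                                up_phyla = c("Bacteroidetes", "Proteobacteria"),
                                down_phyla = c("Firmicutes", "Actinobacteria")) {
  stopifnot(inherits(reference, "reference_set"))
  n_pathways <- check_count(n_pathways, "n_pathways", min = 1L)
  bias <- check_number(bias, "bias", min = 0)
  set.seed(check_count(seed, "seed", min = 0L))

  h1 <- rep(names(PATHWAY_H2), length.out = n_pathways)
  h2 <- vapply(seq_len(n_pathways), function(i) {
    subs <- PATHWAY_H2[[h1[i]]]
    subs[((i - 1L) %/% length(PATHWAY_H2)) %% length(subs) + 1L]
  }, character(1))
  pathway_id <- sprintf("pw%03d", seq_len(n_pathways))

  tax <- reference$taxonomy
  species <- tax$species_id[tax$domain == "prokaryote"]
  phylum <- tax$phylum[match(species, tax$species_id)]
  grid <- expand.grid(species_id = species, pathway_id = pathway_id,
                      stringsAsFactors = FALSE)
  base <- stats::runif(nrow(grid))
  g_h1 <- h1[match(grid$pathway_id, pathway_id)]
  g_ph <- phylum[match(grid$species_id, species)]
  exponent <- rep(1, nrow(grid))
  sel <- g_h1 == "biosynthesis"
  exponent[sel & g_ph %in% up_phyla] <- 1 / (1 + bias)
  exponent[sel & g_ph %in% down_phyla] <- 1 + bias
  score <- base^exponent
  out <- data.frame(species_id = grid$species_id, pathway_id = grid$pathway_id,
                    score = score, h1 = g_h1,
                    h2 = h2[match(grid$pathway_id, pathway_id)],
                    stringsAsFactors = FALSE)
  class(out) <- c("pathway_db", "data.frame")
  out
}

#' Generate synthetic clinical component tables
#'
#' Per donor and timepoint: 28-joint tender and swollen counts (integers
#' 0..28), ESR (mm/h, > 0), CRP (mg/dL, >= 0), patient global health GH
#' (0..100 mm) and patient/physician global assessments PGA/EGA (0..10 cm).
#' RA donors start at inflammatory levels; the \code{improvement} effect is
#' applied multiplicatively to the expected component levels across
#' timepoints (factor 1 at the first timepoint decaying geometrically to
#' \code{improvement} at the last; \code{improvement = 1} leaves expectations
#' stationary). MetS donors stay at non-inflammatory levels throughout.
#'
#' @param design a \code{\link{cohort_design}} data.frame.
#' @param effect_config list with \code{improvement} (default 0.55) and
#'   optionally \code{timepoints} (default T0..T3).
#' @param seed integer seed.
#' @return data.frame: donor_id, group, timepoint, TJC28, SJC28, ESR, CRP,
#'   GH, PGA, EGA.
#' @export
generate_clinical_components <- function(design, effect_config = list(),
                                         seed = 1L) {
  stopifnot(is.data.frame(design))
  cfg <- utils::modifyList(list(improvement = 0.55,
                                timepoints = c("T0", "T1", "T2", "T3")),
                           effect_config)
  set.seed(check_count(seed, "seed", min = 0L))
  tps <- cfg$timepoints
  nt <- length(tps)
  fac <- cfg$improvement^(seq(0, 1, length.out = max(nt, 2L))[seq_len(nt)])

  rows <- list()
  for (i in seq_len(nrow(design))) {
    ra <- design$group[i] == "RA"
    p_joint <- if (ra) stats::runif(1, 0.1, 0.35) else 0.01
    esr0 <- if (ra) stats::rlnorm(1, log(28), 0.4) else stats::rlnorm(1, log(12), 0.3)
    crp0 <- if (ra) stats::rgamma(1, shape = 2, scale = 0.8) else stats::rgamma(1, 1.2, scale = 0.2)
    gh0 <- if (ra) stats::runif(1, 30, 80) else stats::runif(1, 5, 30)
    for (t in seq_len(nt)) {
      f <- if (ra) fac[t] else 1
      rows[[length(rows) + 1L]] <- data.frame(
        donor_id = design$donor_id[i], group = design$group[i],
        timepoint = tps[t],
        TJC28 = stats::rbinom(1, 28, p_joint * f),
        SJC28 = stats::rbinom(1, 28, 0.7 * p_joint * f),
        ESR = max(1, stats::rnorm(1, esr0 * f^0.5, 3)),
        CRP = max(0, stats::rnorm(1, crp0 * f, 0.15)),
        GH = min(100, max(0, stats::rnorm(1, gh0 * f, 6))),
        PGA = min(10, max(0, stats::rnorm(1, gh0 * f / 10, 0.7))),
        EGA = min(10, max(0, stats::rnorm(1, gh0 * f / 12, 0.6))),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Generate a synthetic cytometric population table
#'
#' Per sample (donor x timepoint), non-negative population fractions of
#' leukocytes summing to 1. Each donor carries a stable individual profile
#' (population-wise lognormal deviation from the cohort's expected fractions,
#' sd \code{sd_donor}) around which the repeated timepoint measurements
#' scatter with smaller within-donor noise (sd \code{sd_within}), emulating
#' longitudinal cytometric data where pairing across timepoints is
#' informative. One designated population receives the injected effect of a
#' maturing monocyte subset: an RA baseline deficit relative to MetS
#' (\code{ra_deficit} < 1 multiplies its expected fraction at T0) that
#' recovers during fasting (halfway at T1, fully at T2 and later). With
#' \code{ra_deficit = 1} no effect is injected and the table is a pure null.
#'
#' @param design a \code{\link{cohort_design}} data.frame.
#' @param n_populations number of populations (default 110).
#' @param effect_config list with \code{target_population} (index, default 1),
#'   \code{ra_deficit} (default 0.5), \code{sd_donor} (default 0.4),
#'   \code{sd_within} (default 0.2) and optionally \code{timepoints}
#'   (default T0, T1, T2).
#' @param seed integer seed.
#' @return list of class \code{population_table}: \code{fractions} (matrix
#'   samples x populations, rows summing to 1) and \code{samples}
#'   (data.frame: sample_id, donor_id, group, timepoint, leukocyte_count).
#' @export
generate_cytometry_table <- function(design, n_populations = 110L,
                                     effect_config = list(), seed = 1L) {
  stopifnot(is.data.frame(design))
  n_populations <- check_count(n_populations, "n_populations", min = 2L)
  cfg <- utils::modifyList(list(target_population = 1L, ra_deficit = 0.5,
                                sd_donor = 0.4, sd_within = 0.2,
                                timepoints = c("T0", "T1", "T2")),
                           effect_config)
  set.seed(check_count(seed, "seed", min = 0L))
  tps <- cfg$timepoints
  base <- stats::rexp(n_populations) + 0.2
  base <- base / sum(base)
  tgt <- cfg$target_population
  recovery <- stats::setNames(c(0, 0.5, 1, 1)[seq_along(tps)], tps)

  n_samp <- nrow(design) * length(tps)
  fr <- matrix(0, nrow = n_samp, ncol = n_populations,
               dimnames = list(NULL, sprintf("pop%03d", seq_len(n_populations))))
  meta <- vector("list", n_samp)
  r <- 0L
  for (i in seq_len(nrow(design))) {
    donor_profile <- base * stats::rlnorm(n_populations, 0, cfg$sd_donor)
    for (tp in tps) {
      r <- r + 1L
      mu <- donor_profile
      if (design$group[i] == "RA" && cfg$ra_deficit != 1) {
        m <- cfg$ra_deficit + (1 - cfg$ra_deficit) * recovery[[tp]]
        mu[tgt] <- mu[tgt] * m
      }
      x <- mu * stats::rlnorm(n_populations, 0, cfg$sd_within)
      fr[r, ] <- x / sum(x)
      meta[[r]] <- data.frame(sample_id = sprintf("%s_%s", design$donor_id[i], tp),
                              donor_id = design$donor_id[i],
                              group = design$group[i], timepoint = tp,
                              leukocyte_count = design$leukocyte_count[i],
                              stringsAsFactors = FALSE)
    }
  }
  samples <- do.call(rbind, c(meta, list(make.row.names = FALSE)))
  rownames(fr) <- samples$sample_id
  structure(list(fractions = fr, samples = samples,
                 target_population = colnames(fr)[tgt]),
            class = "population_table")
}

#' @export
print.population_table <- function(x, ...) {
  cat(sprintf("population_table: %d samples x %d populations\n",
              nrow(x$fractions), ncol(x$fractions)))
  invisible(x)
}
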