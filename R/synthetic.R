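#' Generate a synthetic species reference (templates + taxonomy)
#'
#' Builds a local reference of fixed-length amplicon template sequences with a
#' five-rank taxonomy (domain, phylum, family, genus, species). Prokaryote
#' species are spread over the phyla Firmicutes, Bacteroidetes, Proteobacteria,
#' Actinobacteria and Verrucomicrobia; a configurable fraction of species forms
#' a eukaryote block (Ascomycota/Basidiomycota). Species are grouped into
#' genera: the first species of a genus carries the genus ancestor template,
#' each further species substitutes exactly
#' \code{round(within_genus_divergence * amplicon_length)} positions (always to
#' a different base, at positions disjoint between siblings), so within-genus
#' template distances are controlled while templates of different genera are
#' independent random sequences (expected pairwise divergence 0.75).
#'
#' @param n_species number of species (>= 2).
#' @param amplicon_length template length in nt (default 200).
#' @param within_genus_divergence fraction of positions substituted per
#'   non-founder species, in (0, 1].
#' @param seed integer seed; output is deterministic given the seed.
#' @param eukaryote_fraction fraction of species placed in the eukaryote block.
#' @param genus_size species per genus (default 2).
#' @return An object of class \code{reference_set}: list with \code{taxonomy}
#'   (data.frame: species_id, domain, phylum, family, genus, species) and
#'   \code{templates} (named character vector).
#' @export
generate_reference <- function(n_species = 20L, amplicon_length = 200L,
                               within_genus_divergence = 0.1, seed = 1L,
                               eukaryote_fraction = 0.2, genus_size = 2L) {
  n_species <- check_count(n_species, "n_species")
  if (n_species < 2L) stopf("'n_species' must be >= 2")
  L <- check_count(amplicon_length, "amplicon_length", min = 10L)
  d <- check_number(within_genus_divergence, "within_genus_divergence")
  if (d <= 0 || d > 1) stopf("'within_genus_divergence' must be in (0, 1]")
  genus_size <- check_count(genus_size, "genus_size")
  set.seed(check_count(seed, "seed", min = 0L))

  n_euk <- round(eukaryote_fraction * n_species)
  if (n_euk == n_species) n_euk <- n_species - 1L
  n_pro <- n_species - n_euk
  pro_phyla <- c("Firmicutes", "Bacteroidetes", "Proteobacteria",
                 "Actinobacteria", "Verrucomicrobia")
  euk_phyla <- c("Ascomycota", "Basidiomycota")

  assign_block <- function(n, phyla, genus_size) {
    n_phyla <- min(length(phyla), max(1L, n %/% genus_size))
    sizes <- diff(floor(seq(0, n, length.out = n_phyla + 1L)))
    rep(phyla[seq_len(n_phyla)], times = sizes)
  }
  phylum <- c(assign_block(n_pro, pro_phyla, genus_size),
              if (n_euk > 0) assign_block(n_euk, euk_phyla, genus_size))
  domain <- c(rep("prokaryote", n_pro), rep("eukaryote", n_euk))

  k_sub <- max(1L, round(d * L))
  species_id <- sprintf("sp%03d", seq_len(n_species))
  genus <- character(n_species)
  family <- character(n_species)
  templates <- character(n_species)
  g_counter <- 0L
  for (ph in unique(phylum)) {
    idx <- which(phylum == ph)
    genus_of <- (seq_along(idx) - 1L) %/% genus_size + 1L
    for (g in unique(genus_of)) {
      g_counter <- g_counter + 1L
      gi <- idx[genus_of == g]
      ancestor_codes <- sample.int(4L, L, replace = TRUE)
      positions_used <- integer(0)
      for (j in seq_along(gi)) {
        if (j == 1L) {
          codes <- ancestor_codes
        } else {
          avail <- setdiff(seq_len(L), positions_used)
          k <- min(k_sub, length(avail))
          pos <- if (k > 0) sample(avail, k) else integer(0)
          positions_used <- c(positions_used, pos)
          codes <- ancestor_codes
          codes[pos] <- ((codes[pos] - 1L + sample.int(3L, k, replace = TRUE)) %% 4L) + 1L
        }
        templates[gi[j]] <- paste0(DNA_ALPHABET[codes], collapse = "")
        genus[gi[j]] <- sprintf("g%03d", g_counter)
      }
      family[gi] <- sprintf("f%02d_%s", g_counter, substr(ph, 1, 4))
    }
  }
  names(templates) <- species_id
  taxonomy <- data.frame(species_id = species_id, domain = domain,
                         phylum = phylum, family = family, genus = genus,
                         species = sprintf("%s_%s", genus, species_id),
                         stringsAsFactors = FALSE)
  structure(list(taxonomy = taxonomy, templates = templates,
                 amplicon_length = L), class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("reference_set: %d species x %d nt\n", length(x$templates),
              x$amplicon_length))
  print(table(x$taxonomy$phylum))
  invisible(x)
}

#' Design table for a two-group, multi-timepoint cohort
#'
#' @param n_ra,n_mets group sizes (defaults 20 RA, 10 MetS).
#' @param timepoints sampling timepoints (default T0 and T3, the stool
#'   collection points; clinical/cytometric generators may use all four).
#' @param seed integer seed for BMI and leukocyte counts.
#' @return data.frame with donor_id, group, BMI (kg/m^2; MetS centred at 35,
#'   RA at 25) and leukocyte_count (cells/nL), plus an attribute
#'   \code{timepoints}.
#' @export
cohort_design <- function(n_ra = 20L, n_mets = 10L,
                          timepoints = c("T0", "T3"), seed = 1L) {
  n_ra <- check_count(n_ra, "n_ra"); n_mets <- check_count(n_mets, "n_mets", min = 0L)
  set.seed(check_count(seed, "seed", min = 0L))
  donor_id <- c(sprintf("RA_%02d", seq_len(n_ra)),
                if (n_mets > 0) sprintf("MetS_%02d", seq_len(n_mets)))
  group <- c(rep("RA", n_ra), rep("MetS", n_mets))
  bmi <- pmax(17, stats::rnorm(n_ra + n_mets,
                               mean = ifelse(group == "RA", 25, 35), sd = 4))
  leuko <- pmax(2.5, stats::rnorm(n_ra + n_mets, mean = 6.5, sd = 1.5))
  out <- data.frame(donor_id = donor_id, group = group,
                    BMI = round(bmi, 1), leukocyte_count = round(leuko, 2),
                    stringsAsFactors = FALSE)
  attr(out, "timepoints") <- timepoints
  out
}

default_effect_config <- function() {
  list(phylum_multipliers = c(Firmicutes = 0.6, Actinobacteria = 0.6,
                              Bacteroidetes = 1.8, Verrucomicrobia = 1.8,
                              Proteobacteria = 1.3),
       rare_frequency = 5e-4,
       n_rare_species = 2L,
       rare_carriers = 3L,
       concentration = 1,
       prevalence = c(prokaryote = 0.95, eukaryote = 0.6))
}

#' Generate ground-truth sample compositions for a cohort
#'
#' Draws, per donor and marker, a sparse Dirichlet base composition over the
#' reference species of that marker's domain (16S draws from prokaryotes,
#' ITS/18S from the smaller eukaryote block, emulating lower eukaryote
#' richness), applies per-phylum T3/T0 abundance multipliers for the
#' post-fasting timepoint, and injects designated rare RA-specific species
#' (default frequency 5e-4) into the first \code{rare_carriers} RA donors at
#' T0 only; those species are absent everywhere else, so presence/absence
#' filters can recover them. All compositions are renormalised to sum to 1.
#'
#' @param design a \code{\link{cohort_design}} data.frame.
#' @param reference a \code{\link{generate_reference}} object.
#' @param marker "16S", "ITS" or "18S".
#' @param effect_config list overriding any of: \code{phylum_multipliers}
#'   (named T3/T0 multipliers, must be > 0), \code{rare_frequency},
#'   \code{n_rare_species}, \code{rare_carriers}, \code{concentration}
#'   (Dirichlet), \code{prevalence} (per-domain carriage probability).
#' @param seed integer seed.
#' @return An object of class \code{composition_set}: list with
#'   \code{samples} (data.frame: sample_id, donor_id, group, timepoint,
#'   marker) and \code{frequencies} (named list sample_id -> named frequency
#'   vector over the marker's species, each summing to 1), plus
#'   \code{rare_species} (the injected RA-specific species ids).
#' @export
generate_composition <- function(design, reference, marker = "16S",
                                 effect_config = list(), seed = 1L) {
  stopifnot(inherits(reference, "reference_set"), is.data.frame(design))
  cfg <- utils::modifyList(default_effect_config(), effect_config)
  if (any(cfg$phylum_multipliers <= 0))
    stopf("phylum multipliers must be > 0")
  timepoints <- attr(design, "timepoints") %||% c("T0", "T3")
  set.seed(check_count(seed, "seed", min = 0L))

  tax <- reference$taxonomy
  dom <- if (marker == "16S") "prokaryote" else "eukaryote"
  pool <- tax$species_id[tax$domain == dom]
  if (length(pool) < 2L) stopf("reference has fewer than 2 %s species", dom)
  prev <- cfg$prevalence[[dom]]

  n_rare <- min(cfg$n_rare_species, max(0L, length(pool) - 2L))
  rare_species <- if (dom == "prokaryote" && n_rare > 0) pool[seq_len(n_rare)] else character(0)
  common <- setdiff(pool, rare_species)
  ra_donors <- design$donor_id[design$group == "RA"]
  carriers <- utils::head(ra_donors, cfg$rare_carriers)

  mult <- stats::setNames(rep(1, length(common)), common)
  ph <- tax$phylum[match(common, tax$species_id)]
  known <- ph %in% names(cfg$phylum_multipliers)
  mult[known] <- cfg$phylum_multipliers[ph[known]]

  samples <- list(); freqs <- list()
  for (i in seq_len(nrow(design))) {
    donor <- design$donor_id[i]
    present <- common[stats::runif(length(common)) < prev]
    if (length(present) < 2L) present <- common[seq_len(min(2L, length(common)))]
    alpha <- rep(cfg$concentration, length(present))
    g <- stats::rgamma(length(present), shape = alpha)
    base <- g / sum(g)
    for (tp in timepoints) {
      f <- stats::setNames(rep(0, length(pool)), pool)
      w <- base
      if (tp != "T0") {
        w <- base * mult[present]
        w <- w / sum(w)
      }
      f[present] <- w
      if (tp == "T0" && donor %in% carriers && length(rare_species) > 0) {
        f[rare_species] <- cfg$rare_frequency
        f <- f / sum(f)
      }
      sid <- sprintf("%s_%s_%s", donor, tp, marker)
      samples[[sid]] <- data.frame(sample_id = sid, donor_id = donor,
                                   group = design$group[i], timepoint = tp,
                                   marker = marker, stringsAsFactors = FALSE)
      freqs[[sid]] <- f
    }
  }
  structure(list(samples = do.call(rbind, c(samples, list(make.row.names = FALSE))),
                 frequencies = freqs, rare_species = rare_species,
                 marker = marker), class = "composition_set")
}

#' @export
print.composition_set <- function(x, ...) {
  cat(sprintf("composition_set: %d samples (%s), %d species pool\n",
              nrow(x$samples), x$marker, length(x$frequencies[[1]])))
  invisible(x)
}

#' Simulate error-bearing amplicon reads from a known composition
#'
#' Draws \code{depth} reads from the species templates in proportion to the
#' given composition (multinomial) and applies i.i.d. substitution errors at
#' the given per-base rate (substitutions only, no indels, keeping read
#' length fixed). The species of origin of every read is stored as hidden
#' ground truth for recovery tests; pipeline stages never consume it.
#'
#' @param frequencies named frequency vector (species_id -> fraction, summing
#'   to 1) or a \code{composition_set} plus \code{sample_id}.
#' @param reference a \code{reference_set}; all composition species must exist.
#' @param depth number of reads (>= 1).
#' @param substitution_rate per-base substitution probability in [0, 0.5).
#' @param seed integer seed.
#' @param sample_id sample label used in read ids.
#' @return An object of class \code{read_set}: list with \code{sequences}
#'   (named character vector of exactly \code{depth} reads), \code{sample_id},
#'   \code{truth} (named species_id per read).
#' @export
simulate_reads <- function(frequencies, reference, depth = 2000L,
                           substitution_rate = 0.005, seed = 1L,
                           sample_id = "sample") {
  if (inherits(frequencies, "composition_set")) {
    if (!sample_id %in% names(frequencies$frequencies))
      stopf("sample '%s' not found in composition set", sample_id)
    frequencies <- frequencies$frequencies[[sample_id]]
  }
  stopifnot(inherits(reference, "reference_set"))
  depth <- check_count(depth, "depth", min = 1L)
  rate <- check_number(substitution_rate, "substitution_rate", min = 0)
  if (rate >= 0.5) stopf("'substitution_rate' must be < 0.5")
  unknown <- setdiff(names(frequencies)[frequencies > 0], names(reference$templates))
  if (length(unknown) > 0)
    stopf("unknown species in composition: %s", paste(unknown, collapse = ", "))
  set.seed(check_count(seed, "seed", min = 0L))

  sp <- names(frequencies)
  counts <- as.vector(stats::rmultinom(1L, depth, frequencies))
  origin <- rep(sp, counts)
  L <- reference$amplicon_length
  tcodes <- seq_to_codes(reference$templates[sp], L)
  rownames(tcodes) <- sp
  codes <- tcodes[origin, , drop = FALSE]
  if (rate > 0) {
    err <- which(stats::runif(length(codes)) < rate)
    if (length(err) > 0)
      codes[err] <- ((codes[err] - 1L + sample.int(3L, length(err), replace = TRUE)) %% 4L) + 1L
  }
  ids <- sprintf("%s_r%05d", sample_id, seq_len(depth))
  seqs <- stats::setNames(codes_to_seq(codes), ids)
  structure(list(sequences = seqs, sample_id = sample_id,
                 truth = stats::setNames(origin, ids)),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set '%s': %d reads x %d nt%s\n", x$sample_id,
              length(x$sequences), nchar(x$sequences[[1]]),
              if (!is.null(x$truth)) " (with ground truth)" else ""))
  invisible(x)
}
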