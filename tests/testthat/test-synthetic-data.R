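test_that("reference generation honours divergence, determinism and error contracts", {
  # two species in one genus: second template substitutes exactly d*L positions
  ref2 <- generate_reference(2, 200, 0.5, seed = 1)
  expect_equal(hamming(ref2$templates[[1]], ref2$templates[[2]]), 100)

  ref_a <- generate_reference(20, 200, 0.1, seed = 7)
  ref_b <- generate_reference(20, 200, 0.1, seed = 7)
  expect_identical(ref_a, ref_b)

  expect_error(generate_reference(1, 200, 0.1), "n_species")

  # invariants: unique ids, equal-length ACGT templates, required phyla
  expect_false(anyDuplicated(ref_a$taxonomy$species_id) > 0)
  expect_true(all(nchar(ref_a$templates) == 200))
  expect_false(any(grepl("[^ACGT]", ref_a$templates)))
  expect_true(all(c("Firmicutes", "Bacteroidetes", "Proteobacteria",
                    "Actinobacteria", "Verrucomicrobia") %in%
                    ref_a$taxonomy$phylum))
  expect_true(any(ref_a$taxonomy$domain == "eukaryote"))

  # templates of different genera are far apart (expected divergence 0.75)
  tax <- ref_a$taxonomy
  g1 <- tax$species_id[tax$genus == tax$genus[1]][1]
  other <- tax$species_id[tax$genus != tax$genus[1]][1]
  expect_gt(hamming(ref_a$templates[[g1]], ref_a$templates[[other]]),
            2 * 0.1 * 200)
})

test_that("compositions normalise, respond to multipliers and isolate rare species", {
  ref <- generate_reference(20, 200, 0.1, seed = 1)
  design <- cohort_design(5, 3, seed = 2)
  comp <- generate_composition(design, ref, seed = 3)

  sums <- vapply(comp$frequencies, sum, numeric(1))
  expect_true(all(abs(sums - 1) < 1e-9))

  # identity multipliers: T0 == T3 for donors without rare-species injection
  comp_id <- generate_composition(design, ref, seed = 3,
                                  effect_config = list(
                                    phylum_multipliers = c(Firmicutes = 1),
                                    n_rare_species = 0L))
  d <- design$donor_id[nrow(design)]   # a MetS donor, never a rare carrier
  expect_equal(comp_id$frequencies[[paste0(d, "_T0_16S")]],
               comp_id$frequencies[[paste0(d, "_T3_16S")]])

  # halving Firmicutes and doubling Bacteroidetes flips the phylum ranking
  comp_fx <- generate_composition(design, ref, seed = 3,
                                  effect_config = list(
                                    phylum_multipliers = c(Firmicutes = 0.5,
                                                           Bacteroidetes = 2.0),
                                    n_rare_species = 0L))
  m <- do.call(rbind, comp_fx$frequencies)
  rownames(m) <- names(comp_fx$frequencies)
  roll <- rollup_taxonomy(m, ref, "phylum")
  t3 <- grepl("_T3_", rownames(roll))
  expect_gt(mean(roll[t3, "Bacteroidetes"] / roll[!t3, "Bacteroidetes"]),
            mean(roll[t3, "Firmicutes"] / roll[!t3, "Firmicutes"]))

  # rare species: present only in designated RA donors at T0, at ~5e-4
  rare <- comp$rare_species
  expect_gt(length(rare), 0)
  for (sid in names(comp$frequencies)) {
    meta <- comp$samples[comp$samples$sample_id == sid, ]
    f <- comp$frequencies[[sid]][rare]
    if (meta$group == "RA" && meta$timepoint == "T0" &&
        meta$donor_id %in% design$donor_id[1:3]) {
      expect_true(all(f > 0))
      expect_true(all(f < 1e-3))
    } else {
      expect_true(all(f == 0))
    }
  }

  expect_error(generate_composition(design, ref,
                                    effect_config = list(
                                      phylum_multipliers = c(Firmicutes = 0))),
               "multiplier")
})

test_that("eukaryote markers draw from fewer species than 16S", {
  ref <- generate_reference(30, 200, 0.1, seed = 1, eukaryote_fraction = 0.25)
  design <- cohort_design(6, 3, seed = 2)
  c16 <- generate_composition(design, ref, marker = "16S", seed = 4)
  cits <- generate_composition(design, ref, marker = "ITS", seed = 4)
  rich16 <- mean(vapply(c16$frequencies, richness, integer(1)))
  richits <- mean(vapply(cits$frequencies, richness, integer(1)))
  expect_gt(rich16, richits)
})

test_that("read simulation conserves depth and matches the error model", {
  ref <- generate_reference(5, 200, 0.2, seed = 1, eukaryote_fraction = 0)
  f <- stats::setNames(c(0.4, 0.3, 0.2, 0.05, 0.05), names(ref$templates))

  rs0 <- simulate_reads(f, ref, depth = 50, substitution_rate = 0, seed = 1)
  expect_length(rs0$sequences, 50)
  expect_true(all(rs0$sequences == ref$templates[rs0$truth]))

  rs <- simulate_reads(f, ref, depth = 1000, substitution_rate = 0.01, seed = 2)
  expect_length(rs$sequences, 1000)
  mism <- mapply(hamming, rs$sequences, ref$templates[rs$truth])
  expect_equal(mean(mism), 0.01 * 200, tolerance = 0.15)

  expect_identical(simulate_reads(f, ref, depth = 100, seed = 9),
                   simulate_reads(f, ref, depth = 100, seed = 9))
  bad <- c(f, ghost = 0.1)
  expect_error(simulate_reads(bad / sum(bad), ref, depth = 10), "unknown species")
})

test_that("pathway DB scores sit in [0,1] with a recoverable phylum bias", {
  ref <- generate_reference(20, 200, 0.1, seed = 1)
  db0 <- generate_pathway_db(ref, n_pathways = 60, seed = 2, bias = 0)
  expect_true(all(db0$score >= 0 & db0$score <= 1))
  expect_identical(db0, generate_pathway_db(ref, n_pathways = 60, seed = 2, bias = 0))
  expect_true(all(table(unique(db0[, c("pathway_id", "h1")])$pathway_id) == 1))

  # bias = 0: biosynthesis score means do not differ materially by phylum
  tax <- ref$taxonomy
  bio0 <- db0[db0$h1 == "biosynthesis", ]
  ph <- tax$phylum[match(bio0$species_id, tax$species_id)]
  mu0 <- tapply(bio0$score, ph %in% c("Bacteroidetes", "Proteobacteria"), mean)
  expect_lt(abs(diff(mu0)), 0.1)

  # bias > 0: Bacteroidetes/Proteobacteria biosynthesis scores exceed Firmicutes
  db1 <- generate_pathway_db(ref, n_pathways = 60, seed = 2, bias = 0.8)
  bio1 <- db1[db1$h1 == "biosynthesis", ]
  ph1 <- tax$phylum[match(bio1$species_id, tax$species_id)]
  expect_gt(mean(bio1$score[ph1 %in% c("Bacteroidetes", "Proteobacteria")]),
            mean(bio1$score[ph1 %in% c("Firmicutes", "Actinobacteria")]))
})

test_that("clinical component generator respects ranges and the improvement effect", {
  design <- cohort_design(10, 5, seed = 1)
  tab_id <- generate_clinical_components(design, list(improvement = 1), seed = 3)
  expect_true(all(tab_id$TJC28 >= 0 & tab_id$TJC28 <= 28))
  expect_true(all(tab_id$SJC28 >= 0 & tab_id$SJC28 <= 28))
  expect_true(all(tab_id$ESR > 0))
  expect_true(all(tab_id$CRP >= 0))
  expect_true(all(tab_id$GH >= 0 & tab_id$GH <= 100))

  tab_fx <- generate_clinical_components(design, list(improvement = 0.4), seed = 3)
  das <- function(tab, tp) {
    sub <- tab[tab$timepoint == tp & tab$group == "RA", ]
    stats::median(das28_esr(sub$TJC28, sub$SJC28, sub$ESR, sub$GH))
  }
  expect_lt(das(tab_fx, "T3"), das(tab_fx, "T0"))
})

test_that("cytometry tables normalise, reproduce and carry the injected effect", {
  design <- cohort_design(20, 10, seed = 1)
  tab <- generate_cytometry_table(design, n_populations = 30, seed = 5)
  expect_true(all(abs(rowSums(tab$fractions) - 1) < 1e-9))
  tab2 <- generate_cytometry_table(design, n_populations = 30, seed = 5)
  expect_identical(tab$fractions, tab2$fractions)

  # null table: per-test flag rate stays near alpha
  null_tab <- generate_cytometry_table(design, n_populations = 60,
                                       effect_config = list(ra_deficit = 1),
                                       seed = 6)
  prof <- significance_profile(null_tab)
  rate <- mean(c(prof$sig_t1, prof$sig_t2, prof$sig_welch))
  expect_lt(rate, 0.15)
})
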