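test_that("DAS28-ESR and SDAI formulas match hand computations", {
  expect_equal(das28_esr(0, 0, 1, 0), 0)
  expect_equal(das28_esr(4, 2, 20, 50),
               0.56 * 2 + 0.28 * sqrt(2) + 0.70 * log(20) + 0.014 * 50)
  expect_equal(das28_esr(4, 2, 20, 50), 4.313, tolerance = 1e-3)
  # strictly increasing in each component
  expect_gt(das28_esr(5, 2, 20, 50), das28_esr(4, 2, 20, 50))
  expect_gt(das28_esr(4, 3, 20, 50), das28_esr(4, 2, 20, 50))
  expect_gt(das28_esr(4, 2, 21, 50), das28_esr(4, 2, 20, 50))
  expect_gt(das28_esr(4, 2, 20, 51), das28_esr(4, 2, 20, 50))
  expect_error(das28_esr(4, 2, 0, 50), "ESR")
  expect_error(das28_esr(29, 2, 10, 50), "0..28")

  expect_equal(sdai(0, 0, 0, 0, 0), 0)
  expect_equal(sdai(4, 2, 2.0, 1.5, 1.2), 10.7)
  expect_equal(sdai(1, 2, 3, 0.5, 0.5) + sdai(2, 1, 1, 0.5, 0.5),
               sdai(3, 3, 4, 1, 1))
})

test_that("category thresholds sit exactly at the published boundaries", {
  expect_equal(das28_category(c(2.50, 2.59, 2.6, 3.2, 3.21, 5.1, 5.2)),
               c("remission", "remission", "low", "low", "moderate",
                 "moderate", "high"))
  expect_equal(sdai_category(c(3.3, 3.4, 11, 11.1, 26, 26.1)),
               c("remission", "low", "low", "moderate", "moderate", "high"))
})

test_that("SDAI response classes match the printed patient examples", {
  ra04 <- sdai_category_and_response(3.6, 0.1)
  expect_equal(ra04$percent_change, -97, tolerance = 0.01)
  expect_equal(ra04$response, "MaR")
  expect_true(ra04$remission)

  ra05 <- sdai_category_and_response(19.5, 5.6)
  expect_equal(ra05$percent_change, -71, tolerance = 0.01)
  expect_equal(ra05$response, "MoR")
  expect_false(ra05$remission)

  # boundary behaviour: a reduction of exactly 85% / 70% / 50% is the lower class
  expect_equal(sdai_category_and_response(100, 15)$response, "MoR")
  expect_equal(sdai_category_and_response(100, 30)$response, "MiR")
  expect_equal(sdai_category_and_response(100, 50)$response, "none")
  expect_error(sdai_category_and_response(0, 1), "baseline")
})

test_that("EULAR responses follow the standard grid with the SR override", {
  expect_equal(eular_response(4.46, 2.50), "GR")   # RA_03
  expect_equal(eular_response(3.97, 3.61), "NR")   # RA_14
  expect_equal(eular_response(2.32, 2.18), "SR")   # RA_16: stable remission
  expect_equal(eular_response(1.82, 0.49), "GR")   # RA_04: GR despite remission
  expect_equal(eular_response(7.05, 6.18), "NR")   # RA_02: D 0.87 but high level
  expect_equal(eular_response(5.04, 2.58), "GR")   # RA_05
  expect_equal(eular_response(4.06, 3.17), "MR")   # RA_01: 0.6 < D <= 1.2
})

test_that("seropositivity thresholds reproduce the cohort serology counts", {
  t1 <- read_table1()
  sero <- seropositivity(t1$rf, t1$acpa)
  expect_equal(sum(sero$rf_positive), 12)
  expect_equal(sum(sero$acpa_positive), 12)
  expect_equal(sum(sero$seropositive), 14)
  # the floor value is negative; RF 600 with low ACPA is positive via RF
  expect_false(seropositivity(14, 0.4)$seropositive)
  expect_true(seropositivity(600, 12.4)$seropositive)
  expect_false(seropositivity(600, 12.4)$acpa_positive)
})

test_that("cohort summary reproduces the packaged cohort's printed numbers", {
  t1 <- read_table1()
  expect_equal(nrow(t1), 20)
  summ <- cohort_summary(t1)

  expect_equal(summ$median_delta_das28, -1.23)
  expect_equal(summ$n_improved, 19)
  expect_equal(unname(summ$das28_remission[c("t0", "t3")]), c(2L, 8L))
  expect_equal(summ$sdai_remission_final, 3)
  expect_equal(summ$largest_das28_decrease, -2.90)
  # median SDAI percent change: -42.5 exactly, printed as -43%
  expect_equal(summ$median_sdai_pct_change, -42.5, tolerance = 0.01)
  expect_equal(-floor(abs(summ$median_sdai_pct_change) + 0.5), -43)
  # three non-responders among patients not in baseline remission
  expect_equal(unname(summ$eular[["NR"]]), 3L)
  expect_equal(unname(summ$eular[["SR"]]), 1L)
  expect_equal(sum(summ$eular), 20L)
  # age/BMI descriptives
  expect_equal(unname(round(summ$age[["mean"]])), 51)
  expect_equal(unname(summ$age[["min"]]), 22)
  expect_equal(unname(summ$age[["max"]]), 77)
  expect_equal(unname(round(summ$bmi[["mean"]], 1)), 25.1)
  expect_equal(unname(summ$seropositive[["either"]]), 14L)

  # single-patient table: the median is that patient's delta
  one <- t1[1, ]
  s1 <- cohort_summary(one)
  expect_equal(s1$median_delta_das28, one$das28_t3 - one$das28_t0)
  expect_error(cohort_summary(t1[0, ]), "empty")
})

test_that("generated clinical components score into plausible DAS28/SDAI panels", {
  design <- cohort_design(6, 3, seed = 5)
  comp <- generate_clinical_components(design, seed = 6)
  das <- das28_esr(comp$TJC28, comp$SJC28, comp$ESR, comp$GH)
  sd <- sdai(comp$TJC28, comp$SJC28, comp$PGA, comp$EGA, comp$CRP)
  expect_true(all(das >= 0))
  expect_true(all(sd >= 0))
  # RA improves from T0 to T3 under the default improvement effect
  ra <- comp$group == "RA"
  expect_lt(stats::median(das[ra & comp$timepoint == "T3"]),
            stats::median(das[ra & comp$timepoint == "T0"]))
})
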