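#' DAS28-ESR composite disease activity score
#'
#' Standard four-component formula:
#' 0.56*sqrt(TJC28) + 0.28*sqrt(SJC28) + 0.70*ln(ESR) + 0.014*GH.
#'
#' @param tjc28,sjc28 tender/swollen 28-joint counts (integers 0..28).
#' @param esr erythrocyte sedimentation rate in mm/h (> 0).
#' @param gh patient global health on a 0..100 mm visual analogue scale.
#' @return DAS28-ESR score (vectorised).
#' @examples
#' das28_esr(4, 2, 20, 50)  # 4.313
#' @export
das28_esr <- function(tjc28, sjc28, esr, gh) {
  if (any(tjc28 < 0 | tjc28 > 28) || any(sjc28 < 0 | sjc28 > 28))
    stopf("joint counts must lie in 0..28")
  if (any(esr <= 0)) stopf("ESR must be > 0")
  if (any(gh < 0 | gh > 100)) stopf("GH must lie in 0..100 mm")
  0.56 * sqrt(tjc28) + 0.28 * sqrt(sjc28) + 0.70 * log(esr) + 0.014 * gh
}

#' SDAI simplified disease activity index
#'
#' Linear sum TJC28 + SJC28 + PGA + EGA + CRP with the globals in cm (0..10)
#' and CRP in mg/dL.
#'
#' @param tjc28,sjc28 tender/swollen 28-joint counts.
#' @param pga,ega patient and evaluator global assessment (0..10 cm).
#' @param crp C-reactive protein in mg/dL (>= 0).
#' @return SDAI score (vectorised).
#' @examples
#' sdai(4, 2, 2.0, 1.5, 1.2)  # 10.7
#' @export
sdai <- function(tjc28, sjc28, pga, ega, crp) {
  if (any(tjc28 < 0 | tjc28 > 28) || any(sjc28 < 0 | sjc28 > 28))
    stopf("joint counts must lie in 0..28")
  if (any(pga < 0 | pga > 10) || any(ega < 0 | ega > 10))
    stopf("global assessments must lie in 0..10 cm")
  if (any(crp < 0)) stopf("CRP must be >= 0")
  tjc28 + sjc28 + pga + ega + crp
}

#' DAS28 disease-activity category
#'
#' DAS28-ESR < 2.6 remission; 2.6..3.2 low; > 3.2 and <= 5.1 moderate;
#' > 5.1 high.
#'
#' @param score DAS28-ESR score(s).
#' @return character vector of categories.
#' @export
das28_category <- function(score) {
  if (any(score < 0)) stopf("DAS28 must be >= 0")
  ifelse(score < 2.6, "remission",
         ifelse(score <= 3.2, "low",
                ifelse(score <= 5.1, "moderate", "high")))
}

#' SDAI disease-activity category
#'
#' SDAI <= 3.3 remission; <= 11 low; <= 26 moderate; above that high.
#'
#' @param score SDAI score(s).
#' @return character vector of categories.
#' @export
sdai_category <- function(score) {
  if (any(score < 0)) stopf("SDAI must be >= 0")
  ifelse(score <= 3.3, "remission",
         ifelse(score <= 11, "low",
                ifelse(score <= 26, "moderate", "high")))
}

#' SDAI response classification between two timepoints
#'
#' Percent change 100*(t_end - t_start)/t_start; an SDAI reduction > 85%
#' is a major response (MaR), > 70% up to 85% moderate (MoR), > 50% up to
#' 70% minor (MiR), otherwise none. Remission is attained when the final
#' SDAI is <= 3.3.
#'
#' @param sdai_t0,sdai_t3 SDAI at start and end (start must be > 0).
#' @return list with \code{percent_change}, \code{response} (MaR/MoR/MiR/
#'   none), \code{category} (of the final score) and \code{remission}.
#' @examples
#' sdai_category_and_response(3.6, 0.1)   # -97%, MaR, remission
#' sdai_category_and_response(19.5, 5.6)  # -71%, MoR
#' @export
sdai_category_and_response <- function(sdai_t0, sdai_t3) {
  if (any(sdai_t0 <= 0)) stopf("baseline SDAI must be > 0 for a percent change")
  pct <- 100 * (sdai_t3 - sdai_t0) / sdai_t0
  red <- -pct
  response <- ifelse(red > 85, "MaR",
                     ifelse(red > 70, "MoR",
                            ifelse(red > 50, "MiR", "none")))
  list(percent_change = pct, response = response,
       category = sdai_category(sdai_t3), remission = sdai_t3 <= 3.3)
}

#' EULAR DAS28 response classification
#'
#' Standard EULAR grid on improvement D = DAS28_t0 - DAS28_t3 and attained
#' level: good (GR) when D > 1.2 and the attained DAS28 is <= 3.2; moderate
#' (MR) when D > 1.2 with attained > 3.2, or 0.6 < D <= 1.2 with attained
#' <= 5.1; otherwise no response (NR). Patients already in remission at
#' baseline (both scores < 2.6) whose grid result would be NR are labelled
#' stable remission (SR).
#'
#' @param das28_t0,das28_t3 DAS28 at start and end (vectorised).
#' @return character vector in \{GR, MR, NR, SR\}.
#' @examples
#' eular_response(4.46, 2.50)  # GR
#' eular_response(2.32, 2.18)  # SR
#' @export
eular_response <- function(das28_t0, das28_t3) {
  delta <- das28_t0 - das28_t3
  grid <- ifelse(delta > 1.2 & das28_t3 <= 3.2, "GR",
                 ifelse((delta > 1.2 & das28_t3 > 3.2) |
                          (delta > 0.6 & delta <= 1.2 & das28_t3 <= 5.1),
                        "MR", "NR"))
  ifelse(grid == "NR" & das28_t0 < 2.6 & das28_t3 < 2.6, "SR", grid)
}

#' Rheumatoid factor / ACPA seropositivity flags
#'
#' RF positive strictly above the RF threshold (the default 14 U/L treats
#' the recurring assay floor value as negative), ACPA positive at or above
#' the ACPA threshold; seropositive when either is positive. Both thresholds
#' are inferred conventions, configurable.
#'
#' @param rf rheumatoid factor (U/L).
#' @param acpa anti-citrullinated-protein antibodies (U/L).
#' @param rf_threshold exclusive RF cutoff (default 14).
#' @param acpa_threshold inclusive ACPA cutoff (default 17).
#' @return data.frame: rf_positive, acpa_positive, seropositive.
#' @export
seropositivity <- function(rf, acpa, rf_threshold = 14, acpa_threshold = 17) {
  rf_positive <- rf > rf_threshold
  acpa_positive <- acpa >= acpa_threshold
  data.frame(rf_positive = rf_positive, acpa_positive = acpa_positive,
             seropositive = rf_positive | acpa_positive)
}

#' Cohort-level clinical response summary
#'
#' Summarises a per-patient DAS28/SDAI score table across timepoints:
#' per-patient DAS28 change and SDAI percent change between first and last
#' timepoint (median over patients; the median of an even count is the mean
#' of the two central values), number of improved patients (DAS28 change
#' < 0), DAS28 remission counts per timepoint, SDAI remission count at the
#' final timepoint, EULAR and SDAI response tallies, the largest DAS28
#' decrease, and (when the columns are present) age/BMI statistics and
#' seropositivity counts.
#'
#' @param scores data.frame with one row per patient: \code{donor_id} plus
#'   \code{das28_t0}..\code{das28_t3} and \code{sdai_t0}..\code{sdai_t3}
#'   (missing intermediate timepoints are allowed), optionally \code{age},
#'   \code{bmi}, \code{rf}, \code{acpa}.
#' @param rf_threshold,acpa_threshold passed to \code{\link{seropositivity}}.
#' @return object of class \code{cohort_summary} (a list; see Details) with
#'   a print method.
#' @examples
#' summ <- cohort_summary(read_table1())
#' summ$median_delta_das28   # -1.23
#' @export
cohort_summary <- function(scores, rf_threshold = 14, acpa_threshold = 17) {
  stopifnot(is.data.frame(scores))
  if (nrow(scores) == 0L) stopf("empty score table")
  das_cols <- grep("^das28_t", names(scores), value = TRUE)
  sdai_cols <- grep("^sdai_t", names(scores), value = TRUE)
  if (length(das_cols) < 2L || length(sdai_cols) < 2L)
    stopf("need DAS28 and SDAI columns for at least two timepoints")
  das_cols <- das_cols[order(das_cols)]
  sdai_cols <- sdai_cols[order(sdai_cols)]
  first_das <- das_cols[1]; last_das <- das_cols[length(das_cols)]
  first_sdai <- sdai_cols[1]; last_sdai <- sdai_cols[length(sdai_cols)]

  delta_das <- scores[[last_das]] - scores[[first_das]]
  sdai_resp <- sdai_category_and_response(scores[[first_sdai]],
                                          scores[[last_sdai]])
  eular <- eular_response(scores[[first_das]], scores[[last_das]])

  remission_per_tp <- vapply(das_cols, function(cl)
    sum(das28_category(scores[[cl]]) == "remission"), integer(1))
  names(remission_per_tp) <- sub("^das28_", "", das_cols)

  out <- list(
    n = nrow(scores),
    median_delta_das28 = stats::median(delta_das),
    median_sdai_pct_change = stats::median(sdai_resp$percent_change),
    n_improved = sum(delta_das < 0),
    largest_das28_decrease = min(delta_das),
    das28_remission = remission_per_tp,
    sdai_remission_final = sum(sdai_resp$remission),
    eular = table(factor(eular, levels = c("GR", "MR", "NR", "SR"))),
    sdai_response = table(factor(sdai_resp$response,
                                 levels = c("MaR", "MoR", "MiR", "none"))),
    delta_das28 = stats::setNames(delta_das, scores$donor_id),
    sdai_pct_change = stats::setNames(sdai_resp$percent_change, scores$donor_id)
  )
  if (!is.null(scores$age))
    out$age <- c(mean = mean(scores$age), min = min(scores$age),
                 max = max(scores$age))
  if (!is.null(scores$bmi))
    out$bmi <- c(mean = mean(scores$bmi), min = min(scores$bmi),
                 max = max(scores$bmi))
  if (!is.null(scores$rf) && !is.null(scores$acpa)) {
    sero <- seropositivity(scores$rf, scores$acpa, rf_threshold, acpa_threshold)
    out$seropositive <- c(rf = sum(sero$rf_positive),
                          acpa = sum(sero$acpa_positive),
                          either = sum(sero$seropositive))
  }
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d patients\n", x$n))
  cat(sprintf("  median DAS28 change (last - first): %.2f\n", x$median_delta_das28))
  cat(sprintf("  median SDAI percent change: %.1f%%\n", x$median_sdai_pct_change))
  cat(sprintf("  improved (DAS28 change < 0): %d of %d\n", x$n_improved, x$n))
  cat(sprintf("  largest DAS28 decrease: %.2f\n", x$largest_das28_decrease))
  cat("  DAS28 remission per timepoint: ",
      paste(sprintf("%s=%d", names(x$das28_remission), x$das28_remission),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  SDAI remission at final timepoint: %d\n", x$sdai_remission_final))
  cat("  EULAR response: ",
      paste(sprintf("%s=%d", names(x$eular), as.integer(x$eular)),
            collapse = ", "), "\n", sep = "")
  cat("  SDAI response: ",
      paste(sprintf("%s=%d", names(x$sdai_response), as.integer(x$sdai_response)),
            collapse = ", "), "\n", sep = "")
  if (!is.null(x$seropositive))
    cat(sprintf("  seropositive: RF %d, ACPA %d, either %d\n",
                x$seropositive[["rf"]], x$seropositive[["acpa"]],
                x$seropositive[["either"]]))
  if (!is.null(x$age))
    cat(sprintf("  age mean/min/max: %.0f/%.0f/%.0f\n",
                x$age[["mean"]], x$age[["min"]], x$age[["max"]]))
  if (!is.null(x$bmi))
    cat(sprintf("  BMI mean/min/max: %.1f/%.1f/%.1f\n",
                x$bmi[["mean"]], x$bmi[["min"]], x$bmi[["max"]]))
  invisible(x)
}

#' Packaged per-patient clinical score table
#'
#' Loads the packaged fixture of per-patient demographics, serology and
#' DAS28/SDAI scores at four timepoints for a 20-patient RA fasting cohort
#' (T0 baseline, T1 early after bowel cleansing, T2 end of fasting, T3 three
#' days after breaking the fast).
#'
#' @return data.frame with donor_id, age, gender, bmi, disease_years, rf,
#'   acpa, prednisolone_mg, das28_t0..t3, sdai_t0..t3.
#' @export
read_table1 <- function() {
  path <- system.file("extdata", "table1.csv", package = "amplisom",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
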