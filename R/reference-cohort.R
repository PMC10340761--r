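#' Clinical characteristics of the reference ccRCC cohort
#'
#' Summary demographics of the 80-patient clear cell renal cell carcinoma
#' (ccRCC) cohort the package models: 31 patients with distant metastases at
#' the time of surgery and 49 without, stratified by TNM stage and by the
#' localisation of metastases. Per-sample data for this cohort are not public;
#' only these group summaries are, and they anchor the synthetic-cohort
#' generator and the cohort-arithmetic checks.
#'
#' @return A data frame with one row per stratum: `stratum` (one of
#'   `"tnm_stage"`, `"metastasis"`, `"metastasis_site"`), `group`, `n`,
#'   `age_mean`, `age_sd`, `n_male`, `n_female`.
#' @examples
#' reference_cohort_characteristics()
#' @export
reference_cohort_characteristics <- function() {
  data.frame(
    stratum = c(rep("tnm_stage", 4), rep("metastasis", 2),
                rep("metastasis_site", 4)),
    group = c("I", "II", "III", "IV",
              "met", "nonmet",
              "lungs", "adrenal", "bones", "other"),
    n = c(20L, 6L, 23L, 31L, 31L, 49L, 19L, 9L, 3L, 4L),
    age_mean = c(60.7, 59.3, 62.3, 59.3, 59.3, 61.3, 60.4, 56.2, 61.0, 57.3),
    age_sd = c(11.1, 8.2, 6.9, 7.7, 7.7, 8.9, 8.3, 8.1, 6.6, 7.0),
    n_male = c(10L, 5L, 16L, 16L, 16L, 31L, 9L, 5L, 1L, 4L),
    n_female = c(10L, 1L, 7L, 15L, 15L, 18L, 10L, 4L, 2L, 0L),
    stringsAsFactors = FALSE
  )
}

#' Per-marker reference values for the thirteen study markers
#'
#' Group medians (non-metastatic vs metastatic), modality and — for the ten
#' markers that passed screening into ROC analysis — the reported AUC, optimal
#' cutoff and sensitivity/specificity at that cutoff, for the reference ccRCC
#' cohort. Expression markers (RQ scale, tumour relative to paired normal) are
#' scored positive at or below their cutoff; methylation markers (methylation
#' index, percent) strictly above theirs.
#'
#' These values parameterise [default_marker_specs()] and supply the published
#' cutoffs used by [builtin_panels()].
#'
#' @return Data frame with columns `marker`, `modality`
#'   (`"expression"`/`"methylation"`), `median_nonmet`, `median_met`, `auc`,
#'   `cutoff`, `sensitivity`, `specificity` (percent; `NA` where no ROC row
#'   was reported).
#' @examples
#' reference_marker_table()
#' @export
reference_marker_table <- function() {
  data.frame(
    marker = c("CA9", "NDUFA4L2", "EGLN3", "BHLHE41",
               "MIR125B1", "MIR137", "MIR375", "MIR193A", "MIR34BC",
               "MIR1258", "MIR107", "MIR203A", "MIR132"),
    modality = c(rep("expression", 4), rep("methylation", 9)),
    median_nonmet = c(92.7, 41.1, 11.4, 3.2,
                      36.27, 38.10, 38.99, 38.99, 35.26, 2.97, 1.62, 3.11, 2.9),
    median_met = c(17.8, 6.5, 2.8, 1.6,
                   66.34, 61.84, 66.19, 67.58, 59.23, 5.19, 2.57, 3.42, 4.17),
    auc = c(0.789, 0.753, 0.818, 0.751,
            0.827, 0.716, 0.706, 0.776, 0.732, 0.644, NA, NA, NA),
    cutoff = c(51.3, 22, 4.2, 2.6,
               55.18, 57.62, 64.29, 34.65, 50.35, 7.15, NA, NA, NA),
    sensitivity = c(87.10, 77.42, 67.74, 87.10,
                    83.87, 70.97, 64.52, 96.77, 77.42, 45.16, NA, NA, NA),
    specificity = c(67.35, 67.35, 87.76, 57.14,
                    71.43, 69.39, 81.63, 48.98, 65.31, 87.76, NA, NA, NA),
    stringsAsFactors = FALSE
  )
}

#' Reported diagnostic performance of the three count-rule panels
#'
#' Sensitivity and specificity (percent) reported for the reference cohort for
#' the three built-in panels: the four-gene expression panel (positive at >= 3
#' of 4 events), the five-gene methylation panel (>= 4 of 5) and the combined
#' nine-gene panel (>= 6 of 9). Together with the group sizes (31 metastatic /
#' 49 non-metastatic) these determine integer confusion matrices via
#' [reconstruct_confusion()], from which the predictive values can be
#' recomputed.
#'
#' @return Data frame with columns `panel`, `n_markers`, `k_events`,
#'   `sensitivity`, `specificity`, `npv`, `ppv` (percent).
#' @examples
#' reference_panel_table()
#' @export
reference_panel_table <- function() {
  data.frame(
    panel = c("EXPR4", "METH5", "COMBINED9"),
    n_markers = c(4L, 5L, 9L),
    k_events = c(3L, 4L, 6L),
    sensitivity = c(74.19, 70.97, 87.10),
    specificity = c(79.59, 81.63, 95.92),
    npv = c(82.98, 81.63, 92.16),
    ppv = c(69.70, 70.97, 93.10),
    stringsAsFactors = FALSE
  )
}

#' Overall male fraction of a summarised cohort
#'
#' Pools male/female counts across the metastasis strata of a cohort summary
#' table and returns the male percentage.
#'
#' @param characteristics A data frame as returned by
#'   [reference_cohort_characteristics()].
#' @param stratum Which stratum to pool over (default `"metastasis"`, whose
#'   groups partition the cohort).
#' @return Male fraction in percent.
#' @examples
#' cohort_male_fraction()  # 58.75
#' @export
cohort_male_fraction <- function(characteristics = reference_cohort_characteristics(),
                                 stratum = "metastasis") {
  rows <- characteristics[characteristics$stratum == stratum, , drop = FALSE]
  100 * sum(rows$n_male) / sum(rows$n_male + rows$n_female)
}

#' Size-weighted mean age of a summarised cohort
#'
#' @inheritParams cohort_male_fraction
#' @return Mean age in years, weighting each group's mean by its size.
#' @examples
#' cohort_mean_age()  # 60.525
#' @export
cohort_mean_age <- function(characteristics = reference_cohort_characteristics(),
                            stratum = "metastasis") {
  rows <- characteristics[characteristics$stratum == stratum, , drop = FALSE]
  stats::weighted.mean(rows$age_mean, rows$n)
}

#' Default marker registry
#'
#' Named character vector mapping each study marker to its modality. The
#' modality fixes the event direction a priori: expression markers are
#' "low-positive" (an event is a value at or below the cutoff), methylation
#' markers "high-positive" (strictly above the cutoff).
#'
#' @return Named character vector, values `"expression"` or `"methylation"`.
#' @examples
#' default_marker_registry()
#' @export
default_marker_registry <- function() {
  ref <- reference_marker_table()
  stats::setNames(ref$modality, ref$marker)
}

# direction implied by modality: expression falls with metastasis,
# methylation rises
modality_direction <- function(modality) {
  ifelse(modality == "expression", "low_positive", "high_positive")
}

# round half away from zero, as in the reported tables (base round() is
# round-half-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
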