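#' CKD-EPI estimated glomerular filtration rate
#'
#' Four-branch CKD-EPI creatinine equation (no race coefficient). The branch
#' is chosen by sex and by whether serum creatinine lies below or above the
#' sex-specific knot (0.7 mg/dL for females, 0.9 mg/dL for males):
#'
#' * female, SCr <= 0.7: `144 * 0.993^age * (SCr/0.7)^-0.329`
#' * female, SCr >  0.7: `144 * 0.993^age * (SCr/0.7)^-1.209`
#' * male,   SCr <= 0.9: `141 * 0.993^age * (SCr/0.9)^-0.411`
#' * male,   SCr >  0.9: `141 * 0.993^age * (SCr/0.9)^-1.209`
#'
#' The equation is continuous at each knot, where the creatinine ratio factor
#' is exactly 1. All arguments are vectorized.
#'
#' @param scr Serum creatinine in mg/dL (> 0).
#' @param age Age in years (>= 0).
#' @param sex `"female"` or `"male"` (recycled).
#' @param male_low_exponent Exponent of the male low-creatinine branch.
#'   Defaults to the published CKD-EPI value -0.411; set to -0.4111 to
#'   reproduce a variant sometimes printed in the clinical literature.
#' @return eGFR in mL/min per 1.73 m^2.
#' @examples
#' egfr_ckd_epi(0.7, 0, "female")  # 144
#' egfr_ckd_epi(0.9, 0, "male")    # 141
#' egfr_ckd_epi(1.4, 50, "female")
#' @export
egfr_ckd_epi <- function(scr, age, sex, male_low_exponent = -0.411) {
  if (any(!is.finite(scr)) || any(scr <= 0)) {
    abort("serum creatinine must be positive")
  }
  if (any(!is.finite(age)) || any(age < 0)) abort("age must be nonnegative")
  sex <- match_sex(sex)
  n <- max(length(scr), length(age), length(sex))
  scr <- rep_len(scr, n); age <- rep_len(age, n); sex <- rep_len(sex, n)
  female <- sex == "female"
  kappa <- ifelse(female, 0.7, 0.9)
  base <- ifelse(female, 144, 141)
  low_exp <- ifelse(female, -0.329, male_low_exponent)
  expo <- ifelse(scr <= kappa, low_exp, -1.209)
  base * 0.993^age * (scr / kappa)^expo
}

match_sex <- function(sex) {
  sex <- tolower(as.character(sex))
  sex[sex %in% c("f", "female")] <- "female"
  sex[sex %in% c("m", "male")] <- "male"
  if (!all(sex %in% c("female", "male"))) {
    abort("sex must be \"female\" or \"male\"")
  }
  sex
}

#' Add eGFR to a subject table
#'
#' Convenience wrapper that appends an `egfr` column computed by
#' [egfr_ckd_epi()] from the `scr`, `age` and `sex` columns.
#'
#' @param subjects Data frame with columns `scr`, `age`, `sex`.
#' @param ... Passed to [egfr_ckd_epi()].
#' @return `subjects` as a tibble with an `egfr` column.
#' @export
add_egfr <- function(subjects, ...) {
  need <- c("scr", "age", "sex")
  if (!all(need %in% names(subjects))) {
    abort("subjects must have scr, age and sex columns")
  }
  subjects <- as_tibble(subjects)
  subjects$egfr <- egfr_ckd_epi(subjects$scr, subjects$age, subjects$sex, ...)
  subjects
}

#' Relative telomere length from qPCR Ct values
#'
#' Computes the T/S ratio `2^-ddCt` where `dCt = mean Ct(T) - mean Ct(S)`
#' (replicates averaged arithmetically per target) and
#' `ddCt = dCt_sample - dCt_standard`. The standard is a reference gDNA pool
#' run on every plate to absorb batch effects; a T/S of 1 means telomere
#' content equal to the standard.
#'
#' @param ct_t,ct_s Numeric vectors of replicate Ct values for the telomere
#'   (T) and single-copy gene (S) assays of one sample.
#' @param standard_ct_t,standard_ct_s Replicate Ct values for the standard.
#' @return T/S ratio (dimensionless, > 0).
#' @examples
#' telomere_ts(c(20.1, 20.0, 19.9), c(18, 18, 18), 21, 19)  # dCt equal -> 1
#' @export
telomere_ts <- function(ct_t, ct_s, standard_ct_t, standard_ct_s) {
  for (v in list(ct_t, ct_s, standard_ct_t, standard_ct_s)) {
    if (length(v) < 1 || any(!is.finite(v))) {
      abort("each target needs at least one finite Ct replicate (standard included)")
    }
    if (any(v <= 0 | v >= 45)) abort("Ct values must lie in (0, 45)")
  }
  d_sample <- mean(ct_t) - mean(ct_s)
  d_standard <- mean(standard_ct_t) - mean(standard_ct_s)
  2^-(d_sample - d_standard)
}

#' T/S ratios for a long-format qPCR plate table
#'
#' @param plate Data frame with columns `sample_id`, `target` (`"T"` or
#'   `"S"`), and `ct`; the standard sample is identified by `standard_id`.
#' @param standard_id Sample id of the inter-plate standard.
#' @return Tibble with `sample_id` and `ts_ratio` (standard excluded).
#' @export
telomere_ts_table <- function(plate, standard_id = "standard") {
  need <- c("sample_id", "target", "ct")
  if (!all(need %in% names(plate))) {
    abort("plate must have sample_id, target and ct columns")
  }
  plate <- as_tibble(plate)
  if (!standard_id %in% plate$sample_id) {
    abort(paste0("standard sample \"", standard_id, "\" missing from plate"))
  }
  std <- plate[plate$sample_id == standard_id, ]
  std_t <- std$ct[std$target == "T"]
  std_s <- std$ct[std$target == "S"]
  plate |>
    filter(.data$sample_id != standard_id) |>
    group_by(.data$sample_id) |>
    summarise(
      ts_ratio = telomere_ts(.data$ct[.data$target == "T"],
                             .data$ct[.data$target == "S"],
                             std_t, std_s),
      .groups = "drop"
    )
}
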