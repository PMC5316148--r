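#' Body mass index from weight and height
#'
#' `weight_kg / (height_cm / 100)^2`, i.e. weight in kilograms over squared
#' height in meters. Height is accepted in centimeters (the unit on a
#' stadiometer) and converted internally. The value is carried unrounded;
#' round to 1 decimal for presentation with [round_half_up()].
#'
#' @param weight_kg weight in kg, positive.
#' @param height_cm standing height in cm, positive.
#' @return BMI in kg/m^2 (vectorized, unrounded).
#' @export
#' @examples
#' round_half_up(compute_bmi(38, 146.2), 1)  # 17.8
compute_bmi <- function(weight_kg, height_cm) {
  if (any(!is.finite(weight_kg)) || any(weight_kg <= 0)) {
    stop("weight_kg must be positive", call. = FALSE)
  }
  if (any(!is.finite(height_cm)) || any(height_cm <= 0)) {
    stop("height_cm must be positive", call. = FALSE)
  }
  weight_kg / (height_cm / 100)^2
}

validate_cohort <- function(cohort) {
  required <- c("child_id", "sex", "age_months", "weight_kg", "height_cm")
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cohort <- as.data.frame(cohort)
  if (nrow(cohort) == 0L) stop("cohort is empty", call. = FALSE)
  cohort$sex <- normalize_sex(cohort$sex)
  if (any(cohort$weight_kg <= 0) || any(cohort$height_cm <= 0)) {
    stop("weight_kg and height_cm must be positive", call. = FALSE)
  }
  cohort
}

#' BMI-for-age z-scores for a cohort
#'
#' Looks up the LMS parameters at each child's completed-month age row and
#' converts the child's BMI to a z-score.
#'
#' @param cohort data.frame with columns `child_id`, `sex`, `age_months`,
#'   `weight_kg`, `height_cm`.
#' @param bmi_ref a BMI-for-age [growth_reference()] covering the cohort's
#'   ages.
#' @return numeric vector of BMI-for-age z-scores, one per child.
#' @export
bmi_zscore <- function(cohort, bmi_ref) {
  cohort <- validate_cohort(cohort)
  lms <- lms_at_age(bmi_ref, cohort$sex, cohort$age_months)
  lms_zscore(compute_bmi(cohort$weight_kg, cohort$height_cm),
             lms$L, lms$M, lms$S)
}

#' Classify overweight by the direct BMI-for-age method
#'
#' The "with BMI calculation" arm: each child's BMI is compared against the
#' +1 SD BMI-for-age cutoff at their sex and completed-month age row. A
#' child strictly exceeding the cutoff is labelled `unhealthy` (overweight,
#' which here includes obesity); at or below it, `healthy`. The strict
#' comparison means a BMI exactly on the cutoff is `healthy`.
#'
#' @inheritParams bmi_zscore
#' @param annotate_obesity also flag BMI above the +2 SD cutoff in an
#'   `obese` column (off by default; the screening comparison is binary).
#' @return the cohort with added columns `bmi` (unrounded), `bmi_z`,
#'   `who_threshold` (the +1 SD BMI cutoff used) and `who_status`
#'   (`"healthy"`/`"unhealthy"`).
#' @export
#' @examples
#' ref <- synthetic_reference("bmi_for_age")
#' boy <- data.frame(child_id = "fig1", sex = "male", age_months = 122,
#'                   weight_kg = 38, height_cm = 146.2)
#' classify_who(boy, ref)[, c("bmi", "who_threshold", "who_status")]
classify_who <- function(cohort, bmi_ref, annotate_obesity = FALSE) {
  cohort <- validate_cohort(cohort)
  lms <- lms_at_age(bmi_ref, cohort$sex, cohort$age_months)
  cohort$bmi <- compute_bmi(cohort$weight_kg, cohort$height_cm)
  cohort$bmi_z <- lms_zscore(cohort$bmi, lms$L, lms$M, lms$S)
  cohort$who_threshold <- lms_value_at_zscore(1, lms$L, lms$M, lms$S)
  cohort$who_status <- ifelse(cohort$bmi > cohort$who_threshold,
                              "unhealthy", "healthy")
  if (annotate_obesity) {
    cohort$obese <- cohort$bmi > lms_value_at_zscore(2, lms$L, lms$M, lms$S)
  }
  if (any(abs(cohort$bmi_z) > 5)) {
    warning(sum(abs(cohort$bmi_z) > 5),
            " child(ren) with |BMI z| > 5 - biologically implausible values",
            call. = FALSE)
  }
  cohort
}
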