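#' Synthetic school-age growth reference (for testing and simulation)
#'
#' Builds a smooth, plausible LMS reference for 5-19 year olds (60-228
#' months, monthly grid, both sexes) for either BMI-for-age or
#' height-for-age. The curves are cubic-spline interpolations through
#' hand-set anchor values chosen to resemble published school-age growth
#' references in shape and scale: height medians rise from ~110 cm at age 5
#' through a pubertal spurt to adult values, BMI medians dip after the
#' adiposity rebound and rise into the low 20s, the BMI Box-Cox power is
#' negative (right-skewed BMI) and its coefficient of variation peaks in
#' early adolescence.
#'
#' This is a SYNTHETIC reference: it is not, and does not reproduce, any
#' published table. It exists so the screening-table construction, the
#' classifiers and the agreement pipeline can be exercised end-to-end
#' without redistributing external reference data. Checks that depend on
#' published cutoff values require the real tables (see [load_who2007()]).
#'
#' @param indicator `"bmi_for_age"` or `"height_for_age"`.
#' @return a [growth_reference()] covering 60-228 months for both sexes,
#'   with the overweight cutoff (+1 SD BMI-for-age) increasing in age.
#' @export
#' @examples
#' ref <- synthetic_reference("bmi_for_age")
#' lms_at_age(ref, "male", 122)
synthetic_reference <- function(indicator = c("bmi_for_age", "height_for_age")) {
  indicator <- match.arg(indicator)
  anchor_age <- seq(60, 228, by = 24)
  anchors <- if (indicator == "height_for_age") {
    list(
      male = list(L = rep(1, 8),
                  M = c(110.0, 121.7, 133.3, 143.7, 156.0, 169.0, 175.0, 176.5),
                  S = c(0.040, 0.041, 0.042, 0.043, 0.044, 0.043, 0.041, 0.040)),
      female = list(L = rep(1, 8),
                    M = c(109.4, 120.8, 132.5, 145.0, 157.0, 161.7, 163.0, 163.2),
                    S = c(0.040, 0.041, 0.042, 0.043, 0.042, 0.040, 0.039, 0.039))
    )
  } else {
    list(
      male = list(L = c(-0.90, -1.15, -1.40, -1.60, -1.75, -1.80, -1.75, -1.65),
                  M = c(15.25, 15.55, 16.05, 16.85, 17.95, 19.20, 20.50, 21.70),
                  S = c(0.085, 0.098, 0.112, 0.125, 0.133, 0.133, 0.128, 0.122)),
      female = list(L = c(-0.90, -1.10, -1.25, -1.35, -1.40, -1.35, -1.25, -1.10),
                    M = c(15.25, 15.45, 16.00, 16.95, 18.20, 19.55, 20.70, 21.40),
                    S = c(0.090, 0.103, 0.116, 0.127, 0.133, 0.132, 0.127, 0.122))
    )
  }
  months <- 60:228
  records <- do.call(rbind, lapply(names(anchors), function(sex) {
    a <- anchors[[sex]]
    data.frame(
      sex = sex,
      age_months = months,
      L = stats::spline(anchor_age, a$L, xout = months, method = "natural")$y,
      M = stats::spline(anchor_age, a$M, xout = months, method = "natural")$y,
      S = stats::spline(anchor_age, a$S, xout = months, method = "natural")$y,
      stringsAsFactors = FALSE
    )
  }))
  growth_reference(records, indicator)
}
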