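#' Specification of a synthetic clinic cohort
#'
#' Parameters of the simulated population. The defaults emulate the
#' validation cohort the pipeline was built for: 168 healthy 6-11 year olds
#' attending a university pediatric dental clinic, ~47.6% female, ages
#' uniform on 72-143 completed months, BMI-for-age z-scores distributed
#' N(0.4, 1.0^2), height-for-age z-scores N(0.2, 1.0^2) (placing mean height
#' slightly above the reference median, consistent with that cohort's
#' descriptives), and a height-BMI z correlation of 0.3.
#'
#' Height z-scores are constrained (by rejection sampling) to the height
#' span the screening instrument tabulates, i.e. between the 1st and 99th
#' reference height percentiles: in the validation cohort every child was
#' locatable in the screening tables, so the emulated population contains
#' only instrument-measurable heights. The truncation removes ~2% of the
#' mass and perturbs the height-z moments negligibly.
#'
#' @param n number of children.
#' @param seed integer seed; every draw is reproducible from it.
#' @param age_range_months inclusive integer range of completed months.
#' @param female_fraction probability a child is female.
#' @param bmi_z_mean,bmi_z_sd moments of the BMI-for-age z-score.
#' @param height_z_mean,height_z_sd moments of the height-for-age z-score.
#' @param z_correlation correlation between height and BMI z-scores.
#' @param round_weight,round_height record weight/height to 0.1 resolution
#'   (as a scale and stadiometer would) or keep exact values.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n = 168, seed = 1,
                        age_range_months = c(72, 143),
                        female_fraction = 0.476,
                        bmi_z_mean = 0.4, bmi_z_sd = 1.0,
                        height_z_mean = 0.2, height_z_sd = 1.0,
                        z_correlation = 0.3,
                        round_weight = TRUE, round_height = TRUE) {
  stopifnot(n >= 1, female_fraction >= 0, female_fraction <= 1,
            bmi_z_sd >= 0, height_z_sd >= 0, abs(z_correlation) <= 1,
            length(age_range_months) == 2,
            age_range_months[1] <= age_range_months[2])
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 age_range_months = as.integer(age_range_months),
                 female_fraction = female_fraction,
                 bmi_z_mean = bmi_z_mean, bmi_z_sd = bmi_z_sd,
                 height_z_mean = height_z_mean, height_z_sd = height_z_sd,
                 z_correlation = z_correlation,
                 round_weight = isTRUE(round_weight),
                 round_height = isTRUE(round_height)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort of child anthropometry records
#'
#' Draws ages (uniform integers on the spec's range), sex (Bernoulli), and
#' a bivariate-normal pair of height and BMI z-scores per child, then maps
#' the z-scores through the inverse LMS transforms of the supplied
#' references: height from the height-for-age reference, BMI from the
#' BMI-for-age reference, and weight as `BMI x (height/100)^2`. Deriving
#' weight from simulated BMI (rather than simulating it directly)
#' guarantees the BMI-z marginal and keeps weight-height coherence. Height
#' z-scores are rejection-sampled into the instrument's tabulated
#' percentile span (see [cohort_spec()]).
#'
#' @param spec a [cohort_spec()].
#' @param height_ref height-for-age [growth_reference()] covering the ages.
#' @param bmi_ref BMI-for-age [growth_reference()] covering the ages.
#' @return data.frame of child records: `child_id`, `sex`, `age_months`,
#'   `weight_kg`, `height_cm`, plus the latent `height_z` and `bmi_z` used
#'   to generate them (kept for diagnostics; classification never reads
#'   them). Identical spec (including seed) gives an identical cohort.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 5, seed = 7),
#'                           synthetic_reference("height_for_age"),
#'                           synthetic_reference("bmi_for_age"))
#' cohort[, 1:5]
generate_cohort <- function(spec, height_ref, bmi_ref) {
  stopifnot(inherits(spec, "cohort_spec"))
  for (ref in list(height_ref, bmi_ref)) {
    if (spec$age_range_months[1] < ref$age_range[1] ||
        spec$age_range_months[2] > ref$age_range[2]) {
      stop("the ", ref$indicator, " reference does not cover ages ",
           spec$age_range_months[1], "-", spec$age_range_months[2],
           " months", call. = FALSE)
    }
  }
  set.seed(spec$seed)
  n <- spec$n
  age <- sample(seq(spec$age_range_months[1], spec$age_range_months[2]),
                n, replace = TRUE)
  sex <- ifelse(stats::runif(n) < spec$female_fraction, "female", "male")
  span <- stats::qnorm(c(0.01, 0.99))  # instrument's 1st-99th pct columns
  hz0 <- numeric(n)
  bz0 <- numeric(n)
  todo <- seq_len(n)
  rho <- spec$z_correlation
  while (length(todo)) {
    h <- stats::rnorm(length(todo))
    b <- rho * h + sqrt(1 - rho^2) * stats::rnorm(length(todo))
    hz0[todo] <- h
    bz0[todo] <- b
    hz_try <- spec$height_z_mean + spec$height_z_sd * h
    todo <- todo[hz_try < span[1] | hz_try > span[2]]
  }
  height_z <- spec$height_z_mean + spec$height_z_sd * hz0
  bmi_z <- spec$bmi_z_mean + spec$bmi_z_sd * bz0
  hl <- lms_at_age(height_ref, sex, age)
  bl <- lms_at_age(bmi_ref, sex, age)
  height <- lms_value_at_zscore(height_z, hl$L, hl$M, hl$S)
  bmi <- lms_value_at_zscore(bmi_z, bl$L, bl$M, bl$S)
  if (spec$round_height) height <- round_half_up(height, 1)
  weight <- bmi * (height / 100)^2
  if (spec$round_weight) weight <- round_half_up(weight, 1)
  data.frame(child_id = sprintf("S%04d", seq_len(n)),
             sex = sex, age_months = age,
             weight_kg = weight, height_cm = height,
             height_z = height_z, bmi_z = bmi_z,
             stringsAsFactors = FALSE)
}

#' Descriptive summary of a cohort, stratified by sex and age band
#'
#' Mean and SD of age, weight, height, BMI and BMI-for-age z-score per
#' sex-by-age-band stratum (bands 6-8 years = 72-107 months and 9-11 years
#' = 108-143 months, plus the total column), with a Welch two-sample t-test
#' p-value for the male-female comparison of each variable within each
#' band. Strata with fewer than 2 children get an `NA` SD and are flagged.
#'
#' @param cohort data.frame of child records.
#' @param bmi_ref BMI-for-age [growth_reference()] used to (re)compute
#'   `bmi` and `bmi_z` if absent.
#' @return a `cohort_summary`: `cells` (stratum, variable, n, mean, sd) and
#'   `gender_tests` (age band, variable, p-value).
#' @export
summarize_cohort <- function(cohort, bmi_ref) {
  cohort <- validate_cohort(cohort)
  if (!all(c("bmi", "bmi_z") %in% names(cohort))) {
    cohort$bmi <- compute_bmi(cohort$weight_kg, cohort$height_cm)
    cohort$bmi_z <- bmi_zscore(cohort, bmi_ref)
  }
  band <- cut(cohort$age_months, breaks = c(72, 108, 144),
              right = FALSE, labels = c("6-8y", "9-11y"))
  vars <- c(age_months = "age_months", weight_kg = "weight_kg",
            height_cm = "height_cm", bmi = "bmi", bmi_z = "bmi_z")
  strata <- c(lapply(levels(band), function(b) {
    lapply(c("male", "female"), function(s) {
      list(name = paste(s, b), idx = which(band == b & cohort$sex == s))
    })
  }), list(list(list(name = "total", idx = seq_len(nrow(cohort))))))
  strata <- unlist(strata, recursive = FALSE)
  cells <- do.call(rbind, lapply(strata, function(st) {
    do.call(rbind, lapply(names(vars), function(v) {
      x <- cohort[[vars[[v]]]][st$idx]
      data.frame(stratum = st$name, variable = v, n = length(x),
                 mean = if (length(x)) mean(x) else NA_real_,
                 sd = if (length(x) >= 2) stats::sd(x) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  gender_tests <- do.call(rbind, lapply(levels(band), function(b) {
    do.call(rbind, lapply(names(vars), function(v) {
      xm <- cohort[[vars[[v]]]][band == b & cohort$sex == "male"]
      xf <- cohort[[vars[[v]]]][band == b & cohort$sex == "female"]
      p <- if (length(xm) >= 2 && length(xf) >= 2) {
        # Welch; essentially-constant data has no defined test -> NA
        tryCatch(stats::t.test(xm, xf)$p.value, error = function(e) NA_real_)
      } else NA_real_
      data.frame(age_band = b, variable = v, p_value = p,
                 stringsAsFactors = FALSE)
    }))
  }))
  structure(list(cells = cells, gender_tests = gender_tests,
                 n = nrow(cohort)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary, n =", x$n, "(mean ± SD)\n")
  wide <- stats::reshape(x$cells[, c("stratum", "variable", "mean", "sd")],
                         idvar = "variable", timevar = "stratum",
                         direction = "wide")
  strata <- unique(x$cells$stratum)
  out <- data.frame(variable = wide$variable)
  for (s in strata) {
    out[[s]] <- sprintf("%.1f ± %.1f",
                        wide[[paste0("mean.", s)]], wide[[paste0("sd.", s)]])
  }
  print(out, row.names = FALSE)
  cat("\nWelch t-test p-values (male vs female):\n")
  print(x$gender_tests, row.names = FALSE)
  invisible(x)
}
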