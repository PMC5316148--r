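test_that("generation is reproducible and respects degenerate specs", {
  refs <- synthetic_refs()
  spec <- cohort_spec(n = 168, seed = 2024)
  c1 <- generate_cohort(spec, refs$height, refs$bmi)
  c2 <- generate_cohort(spec, refs$height, refs$bmi)
  expect_identical(c1, c2)
  expect_equal(nrow(c1), 168)
  expect_true(all(c1$age_months >= 72 & c1$age_months <= 143))
  # zero-variance z's and no correlation: identical (sex, age) children
  # collapse to identical anthropometry
  d <- generate_cohort(cohort_spec(n = 120, seed = 5, bmi_z_sd = 0,
                                   height_z_sd = 0, z_correlation = 0),
                       refs$height, refs$bmi)
  per_cell <- tapply(paste(d$weight_kg, d$height_cm),
                     paste(d$sex, d$age_months),
                     function(x) length(unique(x)))
  expect_true(all(per_cell == 1))
})

test_that("a default-size cohort lands near its BMI z-score target", {
  refs <- synthetic_refs()
  cohort <- generate_cohort(cohort_spec(n = 168, seed = 314),
                            refs$height, refs$bmi)
  # 3 standard errors at sd 1, n 168
  expect_lt(abs(mean(cohort$bmi_z) - 0.4), 3 / sqrt(168))
  # generated z's survive the round trip through measurements: the z
  # recomputed from rounded weight/height stays near the latent draw
  z_back <- bmi_zscore(cohort, refs$bmi)
  expect_lt(max(abs(z_back - cohort$bmi_z)), 0.05)
})

test_that("large cohorts recover the spec moments and correlation", {
  refs <- synthetic_refs()
  cohort <- generate_cohort(cohort_spec(n = 5000, seed = 99),
                            refs$height, refs$bmi)
  se_mean <- 1 / sqrt(5000)
  expect_lt(abs(mean(cohort$bmi_z) - 0.4), 3 * se_mean)
  expect_lt(abs(sd(cohort$bmi_z) - 1.0), 3 * se_mean / sqrt(2) + 0.02)
  expect_lt(abs(cor(cohort$height_z, cohort$bmi_z) - 0.3), 0.05)
  # heights stay inside the instrument's tabulated percentile span
  expect_true(all(cohort$height_z >= qnorm(0.01) - 1e-9))
  expect_true(all(cohort$height_z <= qnorm(0.99) + 1e-9))
})

test_that("raising the BMI z-score mean raises the overweight fraction", {
  refs <- synthetic_refs()
  frac <- sapply(c(0, 0.4, 0.8, 1.2), function(mu) {
    cohort <- generate_cohort(cohort_spec(n = 1500, seed = 7, bmi_z_mean = mu),
                              refs$height, refs$bmi)
    mean(classify_who(cohort, refs$bmi)$who_status == "unhealthy")
  })
  expect_true(all(diff(frac) > 0))
})

test_that("summaries stratify by sex and age band and partition the cohort", {
  refs <- synthetic_refs()
  cohort <- generate_cohort(cohort_spec(n = 168, seed = 21),
                            refs$height, refs$bmi)
  s <- summarize_cohort(cohort, refs$bmi)
  banded <- s$cells[s$cells$stratum != "total", ]
  totals <- s$cells[s$cells$stratum == "total", ]
  ns <- vapply(split(banded$n, banded$stratum), unique, numeric(1))
  expect_equal(sum(ns), 168)  # the four sex-by-band strata partition n
  expect_equal(unique(totals$n), 168)
  expect_equal(nrow(s$gender_tests), 10)  # 2 bands x 5 variables
  expect_true(all(s$gender_tests$p_value > 0 & s$gender_tests$p_value <= 1))
  # identical children have zero dispersion in every cell
  clones <- data.frame(child_id = paste0("k", 1:10), sex = "male",
                       age_months = 100, weight_kg = 30, height_cm = 130)
  sc <- summarize_cohort(clones, refs$bmi)
  expect_true(all(sc$cells$sd[sc$cells$n >= 2] == 0))
})

test_that("the Welch test matches a hand computation on a tiny fixture", {
  refs <- synthetic_refs()
  # two groups engineered in the 6-8 y band
  xm <- c(25, 27, 29, 31)   # mean 28, var 20/3
  xf <- c(24, 26, 28)       # mean 26, var 4
  cohort <- data.frame(
    child_id = paste0("t", 1:7),
    sex = c(rep("male", 4), rep("female", 3)),
    age_months = 90,
    weight_kg = c(xm, xf),
    height_cm = 130
  )
  s <- summarize_cohort(cohort, refs$bmi)
  expect_true(all(is.na(s$gender_tests$p_value[s$gender_tests$variable %in%
                                                 c("age_months", "height_cm")])))
  p <- s$gender_tests$p_value[s$gender_tests$age_band == "6-8y" &
                                s$gender_tests$variable == "weight_kg"]
  # Welch: t = 2 / sqrt(20/12 + 4/3) = 1.1547, df by Welch-Satterthwaite
  se2m <- (20 / 3) / 4
  se2f <- 4 / 3
  tstat <- (28 - 26) / sqrt(se2m + se2f)
  df <- (se2m + se2f)^2 / (se2m^2 / 3 + se2f^2 / 2)
  expect_equal(p, 2 * pt(-abs(tstat), df), tolerance = 1e-10)
})
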