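# Shared fixtures, all built in code.

# tiny 2-sex x 3-age reference in the canonical file dialect
write_tiny_reference <- function(path, sep = ",") {
  lines <- c(
    paste("sex", "age_months", "L", "M", "S", sep = sep),
    paste("male", 120, -1.2, 16.0, 0.11, sep = sep),
    paste("male", 121, -1.2, 16.1, 0.11, sep = sep),
    paste("male", 122, -1.2, 16.2, 0.11, sep = sep),
    paste("female", 120, -1.1, 16.1, 0.12, sep = sep),
    paste("female", 121, -1.1, 16.2, 0.12, sep = sep),
    paste("female", 122, -1.1, 16.3, 0.12, sep = sep)
  )
  writeLines(lines, path)
  path
}

# near-degenerate references: height M = 100 cm at every age/percentile
# (S tiny), +1 SD BMI cutoff = 20 everywhere -> every grid weight 20.0 kg
flat_refs <- function() {
  months <- 60:228
  mk <- function(L, M, S, indicator) {
    growth_reference(
      rbind(data.frame(sex = "male", age_months = months, L = L, M = M, S = S),
            data.frame(sex = "female", age_months = months, L = L, M = M, S = S)),
      indicator
    )
  }
  list(
    # L=1, S=1e-6: value_at_percentile(p) = 100*(1 + 1e-6 z) ~ 100 at 0.1 cm
    height = mk(1, 100, 1e-6, "height_for_age"),
    # L=1, M=10, S=1: +1 SD value = 10*(1+1) = 20 exactly
    bmi = mk(1, 10, 1, "bmi_for_age")
  )
}

# the worked-example lookup: rows 10 / 10.5 y, columns bracketing 146 cm
# with the published grid weights 38.5, 40.6 / 39.4, 40.8 kg
fig1_table <- function() {
  screening_table(
    sex = "male", ages = c(10, 10.5), percentiles = c(25, 50),
    heights = rbind(c(144.4, 148.3), c(144.8, 147.2)),
    weights = rbind(c(38.5, 40.6), c(39.4, 40.8))
  )
}

synthetic_refs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- list(bmi = synthetic_reference("bmi_for_age"),
                     height = synthetic_reference("height_for_age"))
    }
    cache
  }
})

synthetic_tables <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      r <- synthetic_refs()
      cache <<- list(male = build_screening_table(r$bmi, r$height, "male"),
                     female = build_screening_table(r$bmi, r$height, "female"))
    }
    cache
  }
})

# engineer a cohort that the two classifiers cross-classify into the given
# (a, b, c = 0, d) counts; construction is verified cell by cell
make_agreement_cohort <- function(a, b, d, refs = synthetic_refs(),
                                  tables = synthetic_tables()) {
  n <- a + b + d
  target <- rep(c("a", "b", "d"), c(a, b, d))
  # off-row ages and off-column heights so the simplified threshold sits
  # strictly below the direct cutoff weight (the borderline band b lives in)
  ages <- 73 + (seq_len(n) * 7) %% 68
  ages[ages %% 6 == 0] <- ages[ages %% 6 == 0] + 1
  sexes <- rep(c("male", "female"), length.out = n)
  rows <- lapply(seq_len(n), function(i) {
    sex <- sexes[i]; age <- ages[i]
    hl <- lms_at_age(refs$height, sex, age)
    h <- round_half_up(lms_value_at_zscore(0.37, hl$L, hl$M, hl$S), 1)
    bl <- lms_at_age(refs$bmi, sex, age)
    cutoff_w <- lms_value_at_zscore(1, bl$L, bl$M, bl$S) * (h / 100)^2
    simp_w <- locate_grid_cells(tables[[sex]], age, h)$threshold
    stopifnot(simp_w < cutoff_w)  # borderline band must exist
    w <- switch(target[i],
                a = round_half_up(cutoff_w, 1) + 2,
                b = simp_w,  # >= grid, but below the direct cutoff
                d = round_half_up(simp_w, 1) - 1.5)
    data.frame(child_id = sprintf("F%03d", i), sex = sex, age_months = age,
               weight_kg = w, height_cm = h, stringsAsFactors = FALSE)
  })
  cohort <- do.call(rbind, rows)
  chk <- classify_simplified(classify_who(cohort, refs$bmi), tables)
  got <- paste0(ifelse(chk$simplified_status == "unhealthy", "u", "h"),
                ifelse(chk$who_status == "unhealthy", "u", "h"))
  want <- c(a = "uu", b = "uh", d = "hh")[target]
  stopifnot(identical(got, unname(want)))
  cohort
}
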