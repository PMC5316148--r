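test_that("a degenerate reference yields the hand-computable flat grid", {
  refs <- flat_refs()
  tab <- build_screening_table(refs$bmi, refs$height, "male")
  # every column height is 100 cm and the cutoff 20 kg/m^2: w = 20 * 1^2
  expect_true(all(tab$weights == 20.0))
  expect_true(all(tab$heights == 100.0))
  expect_equal(length(tab$ages), 29)  # 5.0-19.0 y in half-year rows
})

test_that("built grids are strictly monotone within rows", {
  for (tab in synthetic_tables()) {
    expect_true(all(apply(tab$heights, 1, function(h) all(diff(h) > 0))))
    expect_true(all(apply(tab$weights, 1, function(w) all(diff(w) > 0))))
    expect_true(all(tab$weights > 0))
  }
})

test_that("build fails when a reference does not cover the age rows", {
  months <- 60:120  # stops at 10 y
  rec <- rbind(data.frame(sex = "male", age_months = months, L = 1, M = 16, S = 0.1),
               data.frame(sex = "female", age_months = months, L = 1, M = 16, S = 0.1))
  short_ref <- growth_reference(rec, "bmi_for_age")
  expect_error(build_screening_table(short_ref, flat_refs()$height, "male"),
               "does not cover month")
})

test_that("grid lookup brackets off-grid ages and heights, 1-4 cells", {
  tab <- synthetic_tables()$male
  # between two rows and two columns: 4 cells, rows 10 and 10.5 y
  lk <- locate_grid_cells(tab, 122, 146)
  expect_equal(nrow(lk$cells), 4)
  expect_setequal(lk$cells$age_years, c(10, 10.5))
  expect_equal(lk$threshold, min(lk$cells$weight_kg))
  expect_equal(lk$height_flag, "in_span")
  # exactly on a row and on a column: one cell
  on <- locate_grid_cells(tab, 120, tab$heights["10", "50"])
  expect_equal(nrow(on$cells), 1)
  expect_equal(on$cells$weight_kg, unname(tab$weights["10", "50"]))
  # on a row, off-column: two cells from that row only
  two <- locate_grid_cells(tab, 120, tab$heights["10", "50"] + 0.3)
  expect_equal(nrow(two$cells), 2)
  expect_true(all(two$cells$age_years == 10))
  expect_error(locate_grid_cells(tab, 59, 120), "outside the table")
})

test_that("heights beyond the column span are clamped and flagged", {
  tab <- synthetic_tables()$male
  low <- locate_grid_cells(tab, 120, tab$heights["10", "1"] - 5)
  expect_equal(low$height_flag, "below_span")
  expect_equal(low$cells$percentile, 1)
  high <- locate_grid_cells(tab, 120, tab$heights["10", "99"] + 5)
  expect_equal(high$height_flag, "above_span")
  expect_equal(high$cells$percentile, 99)
})

test_that("the simplified rule flags weight at or above the minimum grid", {
  tab <- fig1_table()
  boy <- function(w) data.frame(child_id = "fig1", sex = "male",
                                age_months = 122, weight_kg = w,
                                height_cm = 146)
  lk <- locate_grid_cells(tab, 122, 146)
  expect_equal(sort(lk$cells$weight_kg), c(38.5, 39.4, 40.6, 40.8))
  expect_equal(lk$threshold, 38.5)
  expect_equal(classify_simplified(boy(38), tab)$simplified_status, "healthy")
  expect_equal(classify_simplified(boy(38.7), tab)$simplified_status, "unhealthy")
  # a weight above every matched grid dominates all thresholds
  expect_equal(classify_simplified(boy(41.8), tab)$simplified_status, "unhealthy")
  # audit trail records all matched cells
  expect_match(classify_simplified(boy(38), tab)$simplified_cells, "38.5")
})

test_that("tables round-trip losslessly through delimited text", {
  tabs <- synthetic_tables()
  path <- withr::local_tempfile(fileext = ".csv")
  write_screening_table(tabs, path)
  back <- read_screening_table(path)
  for (s in c("male", "female")) {
    expect_equal(back[[s]]$heights, tabs[[s]]$heights)
    expect_equal(back[[s]]$weights, tabs[[s]]$weights)
    expect_equal(back[[s]]$ages, tabs[[s]]$ages)
    expect_equal(back[[s]]$percentiles, tabs[[s]]$percentiles)
  }
  # single-sex files come back as a bare table with 29 age rows
  write_screening_table(tabs$male, path)
  solo <- read_screening_table(path)
  expect_s3_class(solo, "screening_table")
  expect_equal(length(solo$ages), 29)
})

test_that("imports rejecting a hand-edited monotonicity break name the cell", {
  tabs <- synthetic_tables()
  path <- withr::local_tempfile(fileext = ".csv")
  write_screening_table(tabs$male, path)
  long <- read.csv(path)
  i <- which(long$age_years == 10 & long$percentile == 50)
  long$weight_kg[i] <- 5  # force a decrease within the 10 y row
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  expect_error(read_screening_table(path), "decreasing at age row 10")
})

test_that("on-grid children get the same verdict from both classifiers", {
  refs <- synthetic_refs()
  tabs <- synthetic_tables()
  set.seed(55)
  cases <- expand.grid(sex = c("male", "female"),
                       age = c(72, 96, 120, 138),
                       pct = c(3, 25, 50, 95), stringsAsFactors = FALSE)
  for (k in seq_len(nrow(cases))) {
    tab <- tabs[[cases$sex[k]]]
    ri <- match(cases$age[k] / 12, tab$ages)
    ci <- match(cases$pct[k], tab$percentiles)
    h <- tab$heights[ri, ci]
    grid_w <- tab$weights[ri, ci]
    # pick weights clear of the 0.1 kg grid-rounding band around the cutoff
    for (w in c(grid_w - 1, grid_w + 1)) {
      child <- data.frame(child_id = "g", sex = cases$sex[k],
                          age_months = cases$age[k], weight_kg = w,
                          height_cm = h)
      who <- classify_who(child, refs$bmi)$who_status
      simp <- classify_simplified(child, tab)$simplified_status
      expect_identical(simp, who)
    }
  }
})
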