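#' Construct a validated screening table
#'
#' Low-level constructor. A screening table is, for one sex, a grid of
#' screening weights (kg) indexed by half-year age rows and reference height
#' percentile columns: the weight at which a child of that age and height
#' crosses the +1 SD BMI-for-age cutoff. Within every age row both the
#' column heights and the grid weights must be monotone increasing, and all
#' weights positive; violations are reported with their (age row, column)
#' coordinates. Strict increase is asserted on the unrounded grids by
#' [build_screening_table()]; at the stored 0.1 resolution adjacent cells
#' of a (near-)degenerate reference may tie, so the constructor rejects
#' decreases only.
#'
#' @param sex "male" or "female".
#' @param ages numeric vector of age rows in years (e.g. `seq(5, 19, 0.5)`).
#' @param percentiles numeric vector of height percentile column labels.
#' @param heights matrix (rows = ages, cols = percentiles) of column heights
#'   in cm.
#' @param weights matrix of screening weights in kg, same shape.
#' @return an object of class `screening_table`.
#' @seealso [build_screening_table()], [locate_grid_cells()],
#'   [classify_simplified()].
#' @export
screening_table <- function(sex, ages, percentiles, heights, weights) {
  sex <- normalize_sex(sex)
  stopifnot(length(sex) == 1L)
  heights <- as.matrix(heights)
  weights <- as.matrix(weights)
  if (!all(dim(heights) == c(length(ages), length(percentiles))) ||
      !all(dim(weights) == dim(heights))) {
    stop("heights/weights must be ages x percentiles matrices", call. = FALSE)
  }
  if (is.unsorted(ages, strictly = TRUE) ||
      is.unsorted(percentiles, strictly = TRUE)) {
    stop("ages and percentiles must be strictly increasing", call. = FALSE)
  }
  for (i in seq_along(ages)) {
    dh <- diff(heights[i, ])
    if (any(dh < 0)) {
      j <- which(dh < 0)[1]
      stop("column heights decreasing at age row ", ages[i],
           " y, columns ", percentiles[j], "-", percentiles[j + 1],
           call. = FALSE)
    }
    dw <- diff(weights[i, ])
    if (any(dw < 0)) {
      j <- which(dw < 0)[1]
      stop("grid weights decreasing at age row ", ages[i],
           " y, columns ", percentiles[j], "-", percentiles[j + 1],
           call. = FALSE)
    }
  }
  if (any(weights <= 0)) stop("grid weights must be positive", call. = FALSE)
  dimnames(heights) <- dimnames(weights) <-
    list(as.character(ages), as.character(percentiles))
  structure(list(sex = sex, ages = ages, percentiles = percentiles,
                 heights = heights, weights = weights),
            class = "screening_table")
}

#' @export
print.screening_table <- function(x, ...) {
  cat("<screening_table>", x$sex, "-", length(x$ages), "age rows (",
      min(x$ages), "-", max(x$ages), "y ) x", length(x$percentiles),
      "height-percentile columns\n")
  cat("  grid weights", round(min(x$weights), 1), "-",
      round(max(x$weights), 1), "kg\n")
  invisible(x)
}

#' Default height percentile columns of the screening instrument
#'
#' The 11 reference height percentiles used for the table columns.
#' @return numeric vector of 11 percentiles.
#' @export
screening_percentiles <- function() c(1, 3, 5, 15, 25, 50, 75, 85, 95, 97, 99)

#' Build the simplified overweight screening table for one sex
#'
#' For each half-year age row `a` (years) and height percentile `p`, the
#' column height is the height-for-age value at percentile `p` for age
#' `12 a` months, and the screening weight is the +1 SD BMI-for-age cutoff
#' at `12 a` months times the squared column height in meters:
#' `w = bmi_cutoff * (h / 100)^2`. A child of that age whose height sits at
#' that percentile crosses the overweight cutoff exactly at weight `w`, so
#' the table lets raw weight and height be screened with no BMI arithmetic.
#' Heights are rendered to 0.1 cm and weights to 0.1 kg (half-up), the
#' resolution of the measuring instruments.
#'
#' @param bmi_ref BMI-for-age [growth_reference()].
#' @param height_ref height-for-age [growth_reference()].
#' @param sex "male" or "female".
#' @param ages age rows in years; default half-year steps from 5 to 19.
#' @param percentiles height percentile columns; default
#'   [screening_percentiles()].
#' @return a [screening_table()].
#' @export
#' @examples
#' tab <- build_screening_table(synthetic_reference("bmi_for_age"),
#'                              synthetic_reference("height_for_age"), "male")
#' tab
build_screening_table <- function(bmi_ref, height_ref, sex,
                                  ages = seq(5, 19, by = 0.5),
                                  percentiles = screening_percentiles()) {
  sex <- normalize_sex(sex)
  months <- 12 * ages
  for (ref in list(bmi_ref, height_ref)) {
    uncovered <- months[months < ref$age_range[1] | months > ref$age_range[2]]
    if (length(uncovered)) {
      stop("the ", ref$indicator, " reference does not cover month(s) ",
           paste(utils::head(uncovered, 5), collapse = ", "), call. = FALSE)
    }
  }
  hl <- lms_at_age(height_ref, sex, months)
  bl <- lms_at_age(bmi_ref, sex, months)
  cutoff <- lms_value_at_zscore(1, bl$L, bl$M, bl$S)
  heights <- t(vapply(seq_along(ages), function(i) {
    lms_value_at_percentile(percentiles, hl$L[i], hl$M[i], hl$S[i])
  }, numeric(length(percentiles))))
  # strict monotonicity must hold before rendering to 0.1 resolution
  if (any(apply(heights, 1, function(h) any(diff(h) <= 0)))) {
    stop("percentile heights not strictly increasing within an age row",
         call. = FALSE)
  }
  heights <- round_half_up(heights, 1)
  weights <- round_half_up(cutoff * (heights / 100)^2, 1)
  screening_table(sex, ages, percentiles, heights, weights)
}

#' Locate a child's screening grid cells
#'
#' Matches a child's age to the table's half-year rows (one exact row when
#' the age in completed months falls on the half-year grid, otherwise the
#' two bracketing rows) and, within each matched row, the height to the
#' column heights (one exact column, otherwise the two bracketing columns).
#' Heights outside a row's column span are clamped to the nearest edge
#' column and flagged; the screening decision for such a child should be
#' confirmed by direct BMI calculation. The effective decision threshold is
#' the minimum of the 1-4 matched grid weights.
#'
#' @param table a [screening_table()].
#' @param age_months age in completed months (scalar).
#' @param height_cm height in cm (scalar).
#' @return a `grid_lookup`: data.frame `cells` (age row, percentile column,
#'   height, weight per matched cell), `threshold` (min matched weight, kg),
#'   and `height_flag` (`"in_span"`, `"below_span"` or `"above_span"`).
#' @export
locate_grid_cells <- function(table, age_months, height_cm) {
  stopifnot(inherits(table, "screening_table"))
  stopifnot_scalar_number(age_months, "age_months")
  stopifnot_scalar_number(height_cm, "height_cm")
  month_grid <- 12 * table$ages
  if (age_months < month_grid[1] || age_months > month_grid[length(month_grid)]) {
    stop("age ", age_months, " months outside the table's ",
         min(table$ages), "-", max(table$ages), " year rows", call. = FALSE)
  }
  on_row <- which(abs(month_grid - age_months) < 1e-9)
  rows <- if (length(on_row)) on_row else {
    lo <- findInterval(age_months, month_grid)
    c(lo, lo + 1L)
  }
  cells <- list()
  flag <- "in_span"
  for (ri in rows) {
    h <- table$heights[ri, ]
    exact <- which(abs(h - height_cm) < 1e-6)
    if (length(exact)) {
      cols <- exact[1]
    } else if (height_cm < h[1]) {
      cols <- 1L
      flag <- "below_span"
    } else if (height_cm > h[length(h)]) {
      cols <- length(h)
      flag <- "above_span"
    } else {
      lo <- findInterval(height_cm, h)
      cols <- c(lo, lo + 1L)
    }
    cells[[length(cells) + 1L]] <- data.frame(
      age_years = table$ages[ri],
      percentile = table$percentiles[cols],
      height_cm = unname(h[cols]),
      weight_kg = unname(table$weights[ri, cols])
    )
  }
  cells <- do.call(rbind, cells)
  structure(list(cells = cells,
                 threshold = min(cells$weight_kg),
                 height_flag = flag),
            class = "grid_lookup")
}

#' @export
print.grid_lookup <- function(x, ...) {
  cat("<grid_lookup>", nrow(x$cells), "matched cell(s), threshold",
      x$threshold, "kg",
      if (x$height_flag != "in_span") paste0("[", x$height_flag, "]"), "\n")
  print(x$cells, row.names = FALSE)
  invisible(x)
}

#' Classify overweight with the simplified screening table
#'
#' The "without BMI calculation" arm: each child's age row(s) and height
#' column(s) are located in the sex-appropriate table and the child is
#' labelled `unhealthy` if their weight reaches the screening unit grid,
#' i.e. weight >= the minimum matched grid weight. Taking the minimum of
#' the bracketing cells can only lower the threshold relative to the exact
#' cutoff, which is what gives the instrument its screening sensitivity;
#' the direct BMI method ([classify_who()]) keeps a strict `>` at its
#' cutoff, so borderline children may be flagged here but not there.
#'
#' @inheritParams bmi_zscore
#' @param tables a [screening_table()] (single-sex cohort) or a named list
#'   `list(male = , female = )`.
#' @return the cohort with added columns `simplified_threshold` (kg),
#'   `simplified_cells` (matched grid weights, "/"-separated, for audit),
#'   `height_flag`, and `simplified_status` (`"healthy"`/`"unhealthy"`).
#' @export
classify_simplified <- function(cohort, tables) {
  cohort <- validate_cohort(cohort)
  if (inherits(tables, "screening_table")) {
    tables <- stats::setNames(list(tables), tables$sex)
  }
  res <- lapply(seq_len(nrow(cohort)), function(i) {
    tab <- tables[[cohort$sex[i]]]
    if (is.null(tab)) {
      stop("no screening table supplied for sex ", cohort$sex[i],
           call. = FALSE)
    }
    lk <- locate_grid_cells(tab, cohort$age_months[i], cohort$height_cm[i])
    data.frame(simplified_threshold = lk$threshold,
               simplified_cells = paste(format(lk$cells$weight_kg, trim = TRUE),
                                        collapse = "/"),
               height_flag = lk$height_flag)
  })
  res <- do.call(rbind, res)
  cohort <- cbind(cohort, res)
  cohort$simplified_status <-
    ifelse(cohort$weight_kg >= cohort$simplified_threshold,
           "unhealthy", "healthy")
  cohort
}

#' Write screening tables to delimited text
#'
#' Long-format CSV with columns `sex, age_years, percentile, height_cm,
#' weight_kg`, one row per grid cell; a lossless, re-validatable round trip
#' with [read_screening_table()]. One or both sexes may be written to the
#' same file.
#'
#' @param tables a [screening_table()] or a list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_screening_table <- function(tables, path) {
  if (inherits(tables, "screening_table")) tables <- list(tables)
  long <- do.call(rbind, lapply(tables, function(tab) {
    grid <- expand.grid(ai = seq_along(tab$ages),
                        pi = seq_along(tab$percentiles))
    data.frame(sex = tab$sex,
               age_years = tab$ages[grid$ai],
               percentile = tab$percentiles[grid$pi],
               height_cm = tab$heights[cbind(grid$ai, grid$pi)],
               weight_kg = tab$weights[cbind(grid$ai, grid$pi)])
  }))
  long <- long[order(long$sex, long$age_years, long$percentile), ]
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read screening tables back from delimited text
#'
#' Parses the long format written by [write_screening_table()] and
#' re-validates every invariant (strictly increasing heights and weights
#' within each age row); violations are rejected with their cell
#' coordinates.
#'
#' @param path file written by [write_screening_table()].
#' @return a [screening_table()] if the file holds one sex, else a named
#'   list `list(female = , male = )`.
#' @export
read_screening_table <- function(path) {
  if (!file.exists(path)) stop("table file not found: ", path, call. = FALSE)
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sex", "age_years", "percentile", "height_cm", "weight_kg")
  missing_cols <- setdiff(required, names(long))
  if (length(missing_cols)) {
    stop("table file missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- lapply(split(long, normalize_sex(long$sex)), function(block) {
    ages <- sort(unique(block$age_years))
    pcts <- sort(unique(block$percentile))
    if (nrow(block) != length(ages) * length(pcts)) {
      stop("incomplete grid for sex ", block$sex[1], call. = FALSE)
    }
    heights <- matrix(NA_real_, length(ages), length(pcts))
    weights <- matrix(NA_real_, length(ages), length(pcts))
    ai <- match(block$age_years, ages)
    pi <- match(block$percentile, pcts)
    heights[cbind(ai, pi)] <- block$height_cm
    weights[cbind(ai, pi)] <- block$weight_kg
    screening_table(block$sex[1], ages, pcts, heights, weights)
  })
  if (length(out) == 1L) out[[1]] else out
}
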