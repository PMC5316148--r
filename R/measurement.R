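#' Reconcile duplicate anthropometric readings into a recorded value
#'
#' Field protocol for weight (and optionally height) measurement: take two
#' readings after repositioning; if they agree within the tolerance, record
#' their mean. If they disagree, a third reading is required and the mean of
#' the two closest readings is recorded; if the third is equidistant from
#' both earlier readings (no unique closest pair), the mean of all three is
#' recorded. Recorded values are rounded half-up to 0.1, the reading
#' resolution of the scale and stadiometer.
#'
#' Two readings disagreeing beyond the tolerance raise a condition of class
#' `pedscreen_third_reading_required` so a data-entry pipeline can prompt
#' for the third measurement.
#'
#' @param readings numeric vector of 2 or 3 raw readings (kg or cm), all
#'   positive.
#' @param tolerance maximum disagreement (same unit) under which two
#'   readings are accepted; default 0.1.
#' @return the recorded value, rounded half-up to 0.1; always within
#'   `range(readings)`, and invariant to the order of 3 readings.
#' @export
#' @examples
#' reconcile_readings(c(32.5, 32.5))        # 32.5
#' reconcile_readings(c(32.5, 32.8, 32.6))  # closest pair 32.5/32.6 -> 32.6
reconcile_readings <- function(readings, tolerance = 0.1) {
  if (!is.numeric(readings) || !length(readings) %in% 2:3) {
    stop("`readings` must hold 2 or 3 values", call. = FALSE)
  }
  if (any(!is.finite(readings)) || any(readings <= 0)) {
    stop("readings must be positive", call. = FALSE)
  }
  if (!is.finite(tolerance) || tolerance <= 0) {
    stop("tolerance must be positive", call. = FALSE)
  }
  if (length(readings) == 2L) {
    if (abs(readings[1] - readings[2]) > tolerance + 1e-9) {
      stop(structure(
        class = c("pedscreen_third_reading_required", "error", "condition"),
        list(message = sprintf(
               "readings %.1f and %.1f disagree by more than %.1f: third reading required",
               readings[1], readings[2], tolerance),
             call = NULL)))
    }
    return(round_half_up(mean(readings), 1))
  }
  # three readings: mean of the unique closest pair, else mean of all three
  pairs <- utils::combn(3, 2)
  gaps <- apply(pairs, 2, function(p) abs(readings[p[1]] - readings[p[2]]))
  closest <- which(abs(gaps - min(gaps)) < 1e-9)
  if (length(closest) > 1L) {
    return(round_half_up(mean(readings), 1))
  }
  round_half_up(mean(readings[pairs[, closest]]), 1)
}

#' Reconcile a file of duplicate readings
#'
#' Applies [reconcile_readings()] row-wise to a table with columns
#' `child_id, reading1, reading2, reading3` (`reading3` may be blank when
#' the first two agree). Rows whose two readings disagree and lack a third
#' are reported as errors.
#'
#' @param readings data.frame or path to a delimited text file in the
#'   dialect above.
#' @param tolerance passed to [reconcile_readings()].
#' @return data.frame with `child_id` and the `recorded` value.
#' @export
reconcile_cohort_readings <- function(readings, tolerance = 0.1) {
  if (is.character(readings)) {
    readings <- utils::read.csv(readings, stringsAsFactors = FALSE)
  }
  required <- c("child_id", "reading1", "reading2")
  missing_cols <- setdiff(required, names(readings))
  if (length(missing_cols)) {
    stop("readings table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"reading3" %in% names(readings)) readings$reading3 <- NA_real_
  recorded <- vapply(seq_len(nrow(readings)), function(i) {
    r <- c(readings$reading1[i], readings$reading2[i], readings$reading3[i])
    r <- r[!is.na(r)]
    tryCatch(reconcile_readings(r, tolerance), error = function(e) {
      stop("child ", readings$child_id[i], ": ", conditionMessage(e),
           call. = FALSE)
    })
  }, numeric(1))
  data.frame(child_id = readings$child_id, recorded = recorded)
}
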