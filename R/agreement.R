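#' Cross-classify the two screening methods into a 2x2 table
#'
#' Counts the four concordance cells of the simplified-table method against
#' the direct BMI-for-age method (the reference classification):
#' `a` both unhealthy, `b` simplified-unhealthy / reference-healthy,
#' `c` simplified-healthy / reference-unhealthy, `d` both healthy.
#'
#' @param simplified character vector of `"healthy"`/`"unhealthy"` labels
#'   from [classify_simplified()].
#' @param reference character vector of labels from [classify_who()], same
#'   length.
#' @return a `two_by_two` object (see [two_by_two()]); `a+b+c+d` equals the
#'   number of pairs.
#' @export
crosstab <- function(simplified, reference) {
  if (length(simplified) != length(reference) || !length(simplified)) {
    stop("need equal-length, non-empty label vectors", call. = FALSE)
  }
  ok <- c("healthy", "unhealthy")
  if (!all(simplified %in% ok) || !all(reference %in% ok)) {
    stop("labels must be 'healthy' or 'unhealthy'", call. = FALSE)
  }
  two_by_two(a = sum(simplified == "unhealthy" & reference == "unhealthy"),
             b = sum(simplified == "unhealthy" & reference == "healthy"),
             c = sum(simplified == "healthy" & reference == "unhealthy"),
             d = sum(simplified == "healthy" & reference == "healthy"))
}

#' 2x2 concordance table from its four counts
#'
#' @param a both methods unhealthy.
#' @param b test method unhealthy, reference healthy.
#' @param c test method healthy, reference unhealthy.
#' @param d both methods healthy.
#' @return a `two_by_two` object.
#' @export
two_by_two <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) < 1) stop("table must hold at least one pair", call. = FALSE)
  structure(as.list(counts), n = sum(counts), class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(`test` = c("unhealthy", "healthy"),
                              `reference` = c("unhealthy", "healthy")))
  print(m)
  invisible(x)
}

#' Overall, positive and negative percent agreement
#'
#' The agreement measures for a 2x2 cross-classification of two binary
#' screens, with the direct BMI-for-age method as the reference:
#' overall `= 100 (a+d)/n`, positive `= 100 a/(a+c)` (unhealthy children the
#' test also calls unhealthy), negative `= 100 d/(b+d)` (reference-healthy
#' children the test also calls healthy). Values are carried unrounded;
#' integer-rounded presentation values and per-cell percentages of the total
#' are included for reporting. An empty denominator (`a+c = 0` or
#' `b+d = 0`) makes the corresponding statistic undefined (`NA`).
#'
#' @param table a [two_by_two()].
#' @return an `agreement_report`: the table, `n`, unrounded `overall`,
#'   `positive`, `negative` percentages, their integer-rounded
#'   `presentation` values, and `cell_pct`.
#' @export
#' @examples
#' percent_agreement(two_by_two(59, 18, 0, 91))
percent_agreement <- function(table) {
  stopifnot(inherits(table, "two_by_two"))
  n <- attr(table, "n")
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  overall <- 100 * (a + d) / n
  positive <- if (a + c > 0) 100 * a / (a + c) else NA_real_
  negative <- if (b + d > 0) 100 * d / (b + d) else NA_real_
  structure(list(
    table = table, n = n,
    overall = overall, positive = positive, negative = negative,
    presentation = c(overall = round_half_up(overall),
                     positive = round_half_up(positive),
                     negative = round_half_up(negative)),
    cell_pct = 100 * c(a = a, b = b, c = c, d = d) / n
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  t <- x$table
  fmt <- function(k) sprintf("%d (%.2f)", t[[k]], x$cell_pct[[k]])
  cat("Weight status comparison (test vs reference method), n =", x$n, "\n")
  m <- matrix(c(fmt("a"), fmt("c"), fmt("b"), fmt("d")), 2, 2,
              dimnames = list(test = c("unhealthy n (%)", "healthy n (%)"),
                              reference = c("unhealthy", "healthy")))
  print(m, quote = FALSE)
  cat(sprintf("Overall percent agreement  = 100%% x %d/%d = %d%% (%.2f)\n",
              t$a + t$d, x$n, x$presentation["overall"], x$overall))
  if (is.na(x$positive)) {
    cat("Positive percent agreement = undefined (a + c = 0)\n")
  } else {
    cat(sprintf("Positive percent agreement = 100%% x %d/%d = %d%% (%.2f)\n",
                t$a, t$a + t$c, x$presentation["positive"], x$positive))
  }
  if (is.na(x$negative)) {
    cat("Negative percent agreement = undefined (b + d = 0)\n")
  } else {
    cat(sprintf("Negative percent agreement = 100%% x %d/%d = %d%% (%.2f)\n",
                t$d, t$b + t$d, x$presentation["negative"], x$negative))
  }
  invisible(x)
}

#' Cohen's kappa for a 2x2 table (optional extra)
#'
#' Chance-corrected agreement `(p_o - p_e)/(1 - p_e)`. Offered as a
#' supplementary statistic; the primary outputs of this package are the
#' percent-agreement measures of [percent_agreement()].
#'
#' @param table a [two_by_two()].
#' @return kappa in `[-1, 1]`, or `NA` when chance agreement is 1.
#' @export
cohen_kappa <- function(table) {
  stopifnot(inherits(table, "two_by_two"))
  n <- attr(table, "n")
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  po <- (a + d) / n
  pe <- ((a + b) * (a + c) + (c + d) * (b + d)) / n^2
  if (abs(1 - pe) < 1e-12) return(NA_real_)
  (po - pe) / (1 - pe)
}
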