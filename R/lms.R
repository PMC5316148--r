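#' LMS z-score
#'
#' Converts a measurement to a standard-deviation score under the LMS
#' parametrization of a growth reference: a Box-Cox power `L`, median `M`
#' and coefficient of variation `S` at the child's age and sex. For `L != 0`
#' the score is `((x/M)^L - 1) / (L * S)`; in the log-normal limit `L = 0`
#' it is `log(x/M) / S`. The switch to the log branch happens at
#' `|L| < 1e-7` to avoid catastrophic cancellation near zero rather than
#' relying on the numerical limit.
#'
#' @param x measurement in the indicator's units (kg/m^2 for BMI-for-age,
#'   cm for height-for-age); must be positive.
#' @param L Box-Cox power (dimensionless).
#' @param M reference median, same units as `x`; must be positive.
#' @param S coefficient of variation (dimensionless); must be positive.
#' @return the z-score, a finite number, strictly increasing in `x`.
#' @seealso [lms_value_at_zscore()] for the inverse,
#'   [lms_value_at_percentile()] for percentile values.
#' @export
#' @examples
#' lms_zscore(11, L = 1, M = 10, S = 0.1)  # linear case: (11/10 - 1)/0.1 = 1
lms_zscore <- function(x, L, M, S) {
  n <- max(length(x), length(L), length(M), length(S))
  x <- rep_len(x, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("measurement `x` must be positive and finite", call. = FALSE)
  }
  if (any(M <= 0) || any(S <= 0)) {
    stop("LMS parameters require M > 0 and S > 0", call. = FALSE)
  }
  z <- numeric(n)
  log_branch <- abs(L) < 1e-7
  z[log_branch] <- log(x[log_branch] / M[log_branch]) / S[log_branch]
  lb <- !log_branch
  z[lb] <- ((x[lb] / M[lb])^L[lb] - 1) / (L[lb] * S[lb])
  z
}

#' Inverse LMS transform: measurement at a given z-score
#'
#' Returns the measurement value sitting exactly `z` standard deviations from
#' the reference median: `M * (1 + L*S*z)^(1/L)` for `L != 0`,
#' `M * exp(S*z)` for `L = 0` (branch switch at `|L| < 1e-7`). This is the
#' value the +1 SD overweight cutoffs and the screening-table weights are
#' built from.
#'
#' @param z standard-deviation score.
#' @inheritParams lms_zscore
#' @return measurement in the indicator's units;
#'   `lms_value_at_zscore(lms_zscore(x, L, M, S), L, M, S)` recovers `x` to
#'   1e-9 relative tolerance.
#' @export
#' @examples
#' lms_value_at_zscore(0, L = -1.5, M = 16.9, S = 0.11)  # the median, 16.9
lms_value_at_zscore <- function(z, L, M, S) {
  n <- max(length(z), length(L), length(M), length(S))
  z <- rep_len(z, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  if (any(M <= 0) || any(S <= 0)) {
    stop("LMS parameters require M > 0 and S > 0", call. = FALSE)
  }
  x <- numeric(n)
  log_branch <- abs(L) < 1e-7
  x[log_branch] <- M[log_branch] * exp(S[log_branch] * z[log_branch])
  lb <- !log_branch
  base <- 1 + L[lb] * S[lb] * z[lb]
  if (any(base <= 0)) {
    stop("z-score outside the transform's support (1 + L*S*z must be > 0)",
         call. = FALSE)
  }
  x[lb] <- M[lb] * base^(1 / L[lb])
  x
}

#' Measurement value at a reference percentile
#'
#' Maps a percentile to a z-score through the standard normal quantile
#' function and evaluates the inverse LMS transform there. Used to place the
#' height columns of the screening tables at the reference height percentiles.
#'
#' @param p percentile, strictly between 0 and 100.
#' @inheritParams lms_zscore
#' @return measurement at that percentile; monotone increasing in `p`,
#'   and `p = 50` returns the median `M` exactly.
#' @export
#' @examples
#' lms_value_at_percentile(50, L = -1.2, M = 16.0, S = 0.1)  # 16.0
lms_value_at_percentile <- function(p, L, M, S) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 100)) {
    stop("percentile must lie strictly between 0 and 100", call. = FALSE)
  }
  lms_value_at_zscore(stats::qnorm(p / 100), L, M, S)
}
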