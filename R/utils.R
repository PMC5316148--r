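#' Round half away from zero
#'
#' Rounds to `digits` decimals with halves going up (2.5 -> 3), the convention
#' used when recording anthropometric measurements to 0.1 resolution, unlike
#' [base::round()]'s round-half-even. A tiny guard (1e-8) absorbs binary
#' representation error so that e.g. the mean of 32.5 and 32.6, stored as
#' 32.549999..., still rounds to 32.6.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(c(32.55, 19.161, -0.25), 1)
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-8) / scale
}

# normalise sex labels to "male"/"female"; errors on anything else
normalize_sex <- function(sex) {
  s <- tolower(trimws(as.character(sex)))
  out <- rep(NA_character_, length(s))
  out[s %in% c("male", "m", "boy", "boys", "1")] <- "male"
  out[s %in% c("female", "f", "girl", "girls", "2")] <- "female"
  if (anyNA(out)) {
    bad <- unique(s[is.na(out)])
    stop("unrecognised sex label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("`", name, "` must be a single finite number", call. = FALSE)
  }
  invisible(x)
}
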