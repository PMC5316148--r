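#' Construct and validate a growth reference
#'
#' A growth reference is a set of LMS records, one per (sex, age-in-months),
#' for a single indicator. Records are kept sorted by age within sex; both
#' sexes must be present; `M` and `S` must be positive. References whose age
#' grid has gaps (step > 1 month) are flagged `sparse`, in which case
#' [lms_at_age()] interpolates between the bracketing months.
#'
#' @param records data.frame with columns `sex` ("male"/"female"),
#'   `age_months` (integer months), `L`, `M`, `S`.
#' @param indicator `"bmi_for_age"` or `"height_for_age"`.
#' @return an object of class `growth_reference`: the validated record table
#'   plus `indicator`, `age_range` and `sparse` attributes.
#' @seealso [load_reference()] to read one from delimited text,
#'   [lms_at_age()] to query it.
#' @export
growth_reference <- function(records,
                             indicator = c("bmi_for_age", "height_for_age")) {
  indicator <- match.arg(indicator)
  required <- c("sex", "age_months", "L", "M", "S")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop("reference is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- as.data.frame(records)[required]
  records$sex <- normalize_sex(records$sex)
  for (col in c("age_months", "L", "M", "S")) {
    v <- records[[col]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v))) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(v))))
      stop("non-numeric or missing `", col, "` at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }
  if (any(records$M <= 0)) {
    stop("M must be > 0; violated at row(s) ",
         paste(which(records$M <= 0), collapse = ", "), call. = FALSE)
  }
  if (any(records$S <= 0)) {
    stop("S must be > 0; violated at row(s) ",
         paste(which(records$S <= 0), collapse = ", "), call. = FALSE)
  }
  if (any(records$age_months != round(records$age_months))) {
    stop("age_months must be whole months", call. = FALSE)
  }
  key <- paste(records$sex, records$age_months)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate (sex, age_months) row: ", dup, call. = FALSE)
  }
  if (!all(c("male", "female") %in% records$sex)) {
    stop("reference must contain both sexes", call. = FALSE)
  }
  records <- records[order(records$sex, records$age_months), , drop = FALSE]
  rownames(records) <- NULL
  age_range <- range(records$age_months)
  steps <- unlist(tapply(records$age_months, records$sex, diff))
  structure(
    list(records = records,
         indicator = indicator,
         age_range = age_range,
         sparse = length(steps) > 0 && any(steps > 1)),
    class = "growth_reference"
  )
}

#' @export
print.growth_reference <- function(x, ...) {
  cat("<growth_reference> indicator:", x$indicator, "\n")
  cat("  ages", x$age_range[1], "-", x$age_range[2], "months,",
      nrow(x$records), "records",
      if (x$sparse) "(sparse grid, interpolated)" else "(monthly grid)", "\n")
  invisible(x)
}

#' Load an LMS growth reference from delimited text
#'
#' Reads a table with one row per (sex, month). The delimiter (comma or tab)
#' is autodetected from the header line. The default dialect expects columns
#' `sex, age_months, L, M, S`; `col_map` renames differently-labelled columns
#' so published layouts can be ingested without editing the files (e.g. the
#' WHO 2007 expanded tables, which use `Month` for age — see
#' [load_who2007()]).
#'
#' @param path path to the delimited text file.
#' @param indicator `"bmi_for_age"` or `"height_for_age"`.
#' @param col_map named character vector mapping the canonical names
#'   (`sex`, `age_months`, `L`, `M`, `S`) to the column names in the file.
#' @param sex if the file holds a single sex and has no sex column, supply it
#'   here ("male" or "female") — used by the WHO per-sex file layout.
#' @return a validated [growth_reference()].
#' @export
load_reference <- function(path,
                           indicator = c("bmi_for_age", "height_for_age"),
                           col_map = c(sex = "sex", age_months = "age_months",
                                       L = "L", M = "M", S = "S"),
                           sex = NULL) {
  indicator <- match.arg(indicator)
  if (!file.exists(path)) stop("reference file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", strip.white = TRUE)
  if (!is.null(sex)) {
    raw$sex <- normalize_sex(sex)
    col_map["sex"] <- "sex"
  }
  for (canon in names(col_map)) {
    src <- col_map[[canon]]
    if (!src %in% names(raw)) {
      stop("missing column `", src, "` (for ", canon, ") in ", path,
           call. = FALSE)
    }
  }
  records <- data.frame(
    sex = raw[[col_map[["sex"]]]],
    age_months = suppressWarnings(as.numeric(raw[[col_map[["age_months"]]]])),
    L = suppressWarnings(as.numeric(raw[[col_map[["L"]]]])),
    M = suppressWarnings(as.numeric(raw[[col_map[["M"]]]])),
    S = suppressWarnings(as.numeric(raw[[col_map[["S"]]]])),
    stringsAsFactors = FALSE
  )
  for (col in c("age_months", "L", "M", "S")) {
    bad <- which(!is.finite(records[[col]]))
    if (length(bad)) {
      # +1: line numbers in the file are offset by the header
      stop("non-numeric `", col, "` in ", basename(path), " at line(s) ",
           paste(utils::head(bad + 1L, 5), collapse = ", "), call. = FALSE)
    }
  }
  growth_reference(records, indicator)
}

#' Load the WHO 2007 reference from its published per-sex file layout
#'
#' Convenience profile for the publicly distributed WHO 2007 expanded LMS
#' tables, which come as one file per sex and indicator with columns
#' `Month, L, M, S`. Looks in `dir` for files matching
#' `<stub>_boys*` / `<stub>_girls*` where `<stub>` is `bmi` or `hfa`.
#' These tables are NOT bundled with the package; all bundled fixtures are
#' synthetic (see [synthetic_reference()]).
#'
#' @param dir directory holding the WHO files.
#' @param indicator `"bmi_for_age"` or `"height_for_age"`.
#' @return a [growth_reference()], or an error if the files are absent.
#' @export
load_who2007 <- function(dir, indicator = c("bmi_for_age", "height_for_age")) {
  indicator <- match.arg(indicator)
  stub <- if (indicator == "bmi_for_age") "bmi" else "hfa"
  find_one <- function(sex_word) {
    hits <- list.files(dir, pattern = paste0("^", stub, ".*", sex_word),
                       ignore.case = TRUE, full.names = TRUE)
    if (length(hits) != 1L) {
      stop("expected exactly one ", stub, " ", sex_word, " file in ", dir,
           "; found ", length(hits), call. = FALSE)
    }
    hits
  }
  read_sex <- function(path, sex) {
    ref <- utils::read.table(path, header = TRUE,
                             sep = if (grepl("\t", readLines(path, n = 1))) "\t" else ",",
                             stringsAsFactors = FALSE)
    names(ref) <- sub("^Month$", "age_months", names(ref))
    ref$sex <- sex
    ref[c("sex", "age_months", "L", "M", "S")]
  }
  records <- rbind(read_sex(find_one("boys"), "male"),
                   read_sex(find_one("girls"), "female"))
  growth_reference(records, indicator)
}

#' LMS parameters at an age, with interpolation off the month grid
#'
#' Returns the (L, M, S) triple for a sex and age. Tabulated integer months
#' are returned exactly; any other age inside the reference's range gets
#' component-wise linear interpolation between the bracketing tabulated
#' months (the convention of common growth-chart software; published worked
#' examples only ever use exact month rows).
#'
#' @param ref a [growth_reference()].
#' @param sex "male" or "female" (vectorized).
#' @param age_months age in months, possibly fractional (vectorized).
#' @return data.frame with columns `L`, `M`, `S`, one row per query.
#' @export
lms_at_age <- function(ref, sex, age_months) {
  stopifnot(inherits(ref, "growth_reference"))
  n <- max(length(sex), length(age_months))
  sex <- rep_len(normalize_sex(sex), n)
  age_months <- rep_len(age_months, n)
  if (any(age_months < ref$age_range[1] - 1e-9) ||
      any(age_months > ref$age_range[2] + 1e-9)) {
    bad <- age_months[age_months < ref$age_range[1] - 1e-9 |
                      age_months > ref$age_range[2] + 1e-9]
    stop("age ", paste(utils::head(unique(bad), 3), collapse = ", "),
         " months outside reference range [", ref$age_range[1], ", ",
         ref$age_range[2], "]", call. = FALSE)
  }
  out <- data.frame(L = numeric(n), M = numeric(n), S = numeric(n))
  for (s in unique(sex)) {
    idx <- which(sex == s)
    tab <- ref$records[ref$records$sex == s, , drop = FALSE]
    for (col in c("L", "M", "S")) {
      out[[col]][idx] <- stats::approx(tab$age_months, tab[[col]],
                                       xout = age_months[idx],
                                       rule = 1, ties = "ordered")$y
    }
  }
  out
}
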