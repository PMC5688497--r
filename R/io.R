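# Delimited-text input/output for the pipeline schemas.
# CSV dialect: comma separator, period decimal, mandatory header, UTF-8, LF
# line endings; percentages are serialized with 6 decimal places; a missing
# preceding interval is an empty field.

.fmt_num <- function(x) {
  ifelse(is.na(x), "", ifelse(x == round(x) & abs(x) < 1e15,
                              format(x, scientific = FALSE, trim = TRUE),
                              sprintf("%.6f", x)))
}

.write_table <- function(df, path) {
  out <- df
  for (nm in names(out))
    if (is.numeric(out[[nm]])) out[[nm]] <- .fmt_num(out[[nm]])
  con <- file(path, open = "wb")  # binary keeps LF endings on any platform
  on.exit(close(con))
  writeLines(paste(names(out), collapse = ","), con, useBytes = TRUE)
  if (nrow(out))
    writeLines(do.call(paste, c(unname(as.list(out)), sep = ",")), con,
               useBytes = TRUE)
  invisible(path)
}

#' Read and write the individual-level input tables
#'
#' `read_women()` and `read_births()` load and validate the `women.csv` /
#' `births.csv` schemas; the `write_*` counterparts serialize them in the
#' package's CSV dialect (comma, header, UTF-8, LF; empty field for a first
#' birth's missing preceding interval).
#'
#' @param path File path.
#' @return The validated data frame.
#' @export
read_women <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  df$in_union <- df$in_union %in% c("TRUE", "true", "1", TRUE, 1)
  validate_women(df)
}

#' @rdname read_women
#' @export
read_births <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (is.character(df$preceding_interval_months))
    df$preceding_interval_months <-
      suppressWarnings(as.integer(df$preceding_interval_months))
  validate_births(df)
}

#' @rdname read_women
#' @param women,births Data frames in the respective schemas.
#' @export
write_women <- function(women, path) .write_table(validate_women(women), path)

#' @rdname read_women
#' @export
write_births <- function(births, path) .write_table(validate_births(births), path)

#' Read and write survey-aggregate tables
#'
#' The `aggregates.csv` schema: one row per survey with identifiers,
#' covariates, `n_births_window`, `tfr`, and one `<dimension>__<label>`
#' percent column per risk category.
#'
#' @param aggregates Survey-aggregate data frame.
#' @param path File path.
#' @export
write_aggregates <- function(aggregates, path) .write_table(aggregates, path)

#' @rdname write_aggregates
#' @export
read_aggregates <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname write_aggregates
#' @param fits A `birthrisk_fits` object ([fit_all_categories()]).
#' @export
write_fits <- function(fits, path) .write_table(fits_table(fits), path)

#' @rdname write_aggregates
#' @export
write_random_effects <- function(fits, path)
  .write_table(random_effects_table(fits), path)

#' @rdname write_aggregates
#' @param predictions Long prediction table from [run_scenarios()].
#' @export
write_predictions <- function(predictions, path)
  .write_table(predictions, path)

#' Read a flat key-value run configuration
#'
#' Lines of the form `key = value`; `#` starts a comment. List-valued keys
#' (e.g. `scenarios = A,B,C`) are comma-separated. Unknown keys are kept
#' verbatim so callers can extend the format.
#'
#' @param path Path to the configuration file.
#' @return Named list of character values (split on commas).
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3L
  if (any(bad)) stop("malformed config line: ", lines[which(bad)[1L]])
  keys <- trimws(vapply(kv, `[`, "", 2L))
  vals <- trimws(vapply(kv, `[`, "", 3L))
  out <- lapply(vals, function(v) trimws(strsplit(v, ",")[[1]]))
  setNames(out, keys)
}
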