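#' Risk-category taxonomy
#'
#' A category specification fixes, for one risk dimension, an ordered set of
#' labelled half-open intervals `[lower, upper)` that partition the dimension's
#' domain. Three dimensions are used: preceding birth interval in months
#' (`spacing`), mother's completed age at birth in years (`mothers_age`), and
#' birth order (`parity`).
#'
#' @param dimension One of `"spacing"`, `"mothers_age"`, `"parity"`.
#' @param labels Character vector of category labels, ordered.
#' @param lower,upper Numeric vectors of inclusive lower and exclusive upper
#'   bounds, same length as `labels`. Use `Inf` for an unbounded top category.
#' @return An object of class `category_spec`.
#' @examples
#' category_spec("parity", c("first", "2-4", "5+"), c(1, 2, 5), c(2, 5, Inf))
#' @export
category_spec <- function(dimension, labels, lower, upper) {
  dimension <- match.arg(dimension, c("spacing", "mothers_age", "parity"))
  stopifnot(length(labels) == length(lower), length(lower) == length(upper))
  if (any(upper <= lower))
    stop("category bounds must satisfy lower < upper")
  o <- order(lower)
  labels <- labels[o]; lower <- lower[o]; upper <- upper[o]
  # disjoint + exhaustive: consecutive intervals must abut exactly
  if (length(lower) > 1L && any(abs(upper[-length(upper)] - lower[-1L]) > 0))
    stop("categories must be disjoint and exhaustive (abutting half-open intervals)")
  structure(list(dimension = dimension, labels = labels,
                 lower = lower, upper = upper),
            class = "category_spec")
}

#' Default risk-category specifications
#'
#' The standard taxonomy: four preceding-interval categories (under 18 months,
#' 18-23, 24-35, 36 or more), three mother's-age categories (under 18, 18-34,
#' 35 and older, completed years), and three parity categories (first, second
#' to fourth, fifth or later). All bounds are half-open `[lo, hi)`, which makes
#' each dimension's categories disjoint and exhaustive; "24 to 35 months" is
#' the interval `[24, 36)` and "35+" years is `[35, Inf)`.
#'
#' @return Named list of [category_spec()] objects, one per dimension.
#' @export
default_category_specs <- function() {
  list(
    spacing = category_spec("spacing",
                            c("<18mo", "18-23mo", "24-35mo", "36+mo"),
                            c(0, 18, 24, 36), c(18, 24, 36, Inf)),
    mothers_age = category_spec("mothers_age",
                                c("<18", "18-34", "35+"),
                                c(0, 18, 35), c(18, 35, Inf)),
    parity = category_spec("parity",
                           c("first", "2-4", "5+"),
                           c(1, 2, 5), c(2, 5, Inf))
  )
}

#' @export
print.category_spec <- function(x, ...) {
  cat("Risk categories for dimension '", x$dimension, "':\n", sep = "")
  for (i in seq_along(x$labels))
    cat(sprintf("  %-8s [%s, %s)\n", x$labels[i],
                format(x$lower[i]), format(x$upper[i])))
  invisible(x)
}

# label for a vector of values under one spec; NA outside the domain
.classify_values <- function(values, spec) {
  idx <- rep(NA_integer_, length(values))
  for (i in seq_along(spec$labels))
    idx[values >= spec$lower[i] & values < spec$upper[i]] <- i
  spec$labels[idx]
}

#' Classify births into risk categories
#'
#' Assigns each birth a label per dimension: parity from birth order,
#' mother's age from completed years at birth, and preceding-interval category
#' from the months since the next-oldest sibling's birth. First births have no
#' preceding interval, so their spacing label is `NA`.
#'
#' @param births Data frame with columns `birth_order`,
#'   `mother_age_at_birth_years` and `preceding_interval_months` (`NA` exactly
#'   for first births). Typically rows of the `births.csv` schema; see
#'   [read_births()].
#' @param specs Named list of [category_spec()] objects, as from
#'   [default_category_specs()].
#' @return Data frame with one column per dimension (`spacing`, `mothers_age`,
#'   `parity`) holding the assigned labels, one row per birth.
#' @examples
#' b <- data.frame(birth_order = c(5L, 1L, 2L),
#'                 mother_age_at_birth_years = c(17L, 25L, 35L),
#'                 preceding_interval_months = c(12L, NA, 24L))
#' classify_births(b)
#' @export
classify_births <- function(births, specs = default_category_specs()) {
  validate_births(births, require_ids = FALSE)
  n <- nrow(births)
  out <- data.frame(
    spacing = .classify_values(births$preceding_interval_months, specs$spacing),
    mothers_age = .classify_values(births$mother_age_at_birth_years,
                                   specs$mothers_age),
    parity = .classify_values(births$birth_order, specs$parity),
    stringsAsFactors = FALSE
  )
  out$spacing[births$birth_order == 1L] <- NA_character_
  out
}

#' @rdname classify_births
#' @param birth A single-row data frame or a list with the same fields.
#' @return `classify_birth()` returns a named list `dimension -> label`
#'   (spacing entry `NA` for a first birth).
#' @export
classify_birth <- function(birth, specs = default_category_specs()) {
  df <- as.data.frame(birth[c("birth_order", "mother_age_at_birth_years",
                              "preceding_interval_months")])
  res <- classify_births(df, specs)
  as.list(res[1L, , drop = TRUE])
}
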