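#' Fit every risk category
#'
#' Fits the requested model variants independently for each category of each
#' risk dimension (10 categories in the default taxonomy), returning a
#' container that [predict_distribution()] and [run_scenarios()] consume.
#'
#' @param aggregates Survey-aggregate data frame.
#' @param variants Character vector among `"m1"`, `"m2"`, `"m3"`.
#' @param specs Category specifications (see [default_category_specs()]).
#' @param zero_rule Passed to [build_design()].
#' @return An object of class `birthrisk_fits`: a list with elements
#'   `fits[[variant]][[dimension]][[label]]` (each a `risk_loglin`) and
#'   `specs`.
#' @export
fit_all_categories <- function(aggregates, variants = c("m1", "m2", "m3"),
                               specs = default_category_specs(),
                               zero_rule = "continuity") {
  variants <- match.arg(variants, c("m1", "m2", "m3"), several.ok = TRUE)
  fits <- list()
  for (v in variants) {
    fits[[v]] <- list()
    for (s in specs) {
      fits[[v]][[s$dimension]] <- list()
      for (l in s$labels)
        fits[[v]][[s$dimension]][[l]] <-
          risk_loglin(aggregates, s$dimension, l, variant = v,
                      zero_rule = zero_rule)
    }
  }
  structure(list(fits = fits, specs = specs, variants = variants),
            class = "birthrisk_fits")
}

#' @export
print.birthrisk_fits <- function(x, ...) {
  ncat <- sum(vapply(x$specs, function(s) length(s$labels), integer(1)))
  cat(sprintf("birthrisk_fits: %d categories x %d variant(s) [%s]\n",
              ncat, length(x$variants), paste(x$variants, collapse = ", ")))
  one <- x$fits[[1]][[1]][[1]]
  cat(sprintf("  %d surveys, %d countries\n", one$n_surveys, one$n_countries))
  invisible(x)
}

#' Coefficient table for a set of fitted categories
#'
#' One row per (dimension, category, variant) with coefficients, standard
#' errors, p-values and variance components — the `fits.csv` schema.
#'
#' @param x A `birthrisk_fits` object.
#' @return Data frame.
#' @export
fits_table <- function(x) {
  stopifnot(inherits(x, "birthrisk_fits"))
  rows <- list()
  for (v in names(x$fits)) for (d in names(x$fits[[v]]))
    for (l in names(x$fits[[v]][[d]])) {
      f <- x$fits[[v]][[d]][[l]]
      co <- setNames(rep(NA_real_, 4),
                     c("(Intercept)", "mcpr_pct", "pct_permanent", "pct_larc"))
      se <- pv <- co
      co[names(f$coefficients)] <- f$coefficients
      se[names(f$se)] <- f$se
      pv[names(f$p_value)] <- f$p_value
      rows[[length(rows) + 1L]] <- data.frame(
        dimension = d, category = l, variant = v,
        beta0 = co[1], beta1 = co[2], beta2 = co[3], beta3 = co[4],
        se0 = se[1], se1 = se[2], se2 = se[3], se3 = se[4],
        p0 = pv[1], p1 = pv[2], p2 = pv[3], p3 = pv[4],
        sigma2 = f$sigma2, tau2 = if (is.null(f$tau2)) NA_real_ else f$tau2,
        df = f$df, n_surveys = f$n_surveys, n_countries = f$n_countries,
        row.names = NULL, stringsAsFactors = FALSE)
    }
  do.call(rbind, rows)
}

#' Country-effect table for a set of fitted categories
#'
#' One row per (country, dimension, category) with the empirical-Bayes BLUP,
#' for the hierarchical variant — the `random_effects.csv` schema.
#'
#' @param x A `birthrisk_fits` object containing `m3` fits.
#' @return Data frame with columns `country_id`, `dimension`, `category`,
#'   `b_hat`.
#' @export
random_effects_table <- function(x) {
  stopifnot(inherits(x, "birthrisk_fits"))
  if (is.null(x$fits$m3)) stop("no m3 fits present")
  rows <- list()
  for (d in names(x$fits$m3)) for (l in names(x$fits$m3[[d]])) {
    b <- x$fits$m3[[d]][[l]]$ranef
    rows[[length(rows) + 1L]] <- data.frame(
      country_id = names(b), dimension = d, category = l,
      b_hat = unname(b), row.names = NULL, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
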