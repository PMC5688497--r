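#' Contraceptive scale-up scenario
#'
#' A scenario adds `delta_mcpr_pp` percentage points of mCPR, all of it to one
#' method class: scenario A scales up with permanent methods, B with
#' long-acting reversible methods, C with short-term modern methods.
#'
#' @param label `"A"`, `"B"` or `"C"`; determines the target class unless
#'   `target_class` is given explicitly.
#' @param delta_mcpr_pp Increase in mCPR, percentage points (default 10).
#' @param target_class `"permanent"`, `"larc"` or `"short_term"`.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(label = c("A", "B", "C"), delta_mcpr_pp = 10,
                          target_class = NULL) {
  label <- match.arg(label)
  default_class <- c(A = "permanent", B = "larc", C = "short_term")[[label]]
  if (is.null(target_class)) target_class <- default_class
  target_class <- match.arg(target_class, c("permanent", "larc", "short_term"))
  if (!identical(target_class, default_class))
    stop("scenario ", label, " must target ", default_class, " methods")
  if (delta_mcpr_pp <= 0) stop("delta_mcpr_pp must be positive")
  structure(list(label = label, delta_mcpr_pp = delta_mcpr_pp,
                 target_class = target_class), class = "scenario_spec")
}

#' Default scenario set
#'
#' @param delta_mcpr_pp Increase in mCPR applied by each scenario (default 10
#'   percentage points).
#' @return List of the three [scenario_spec()]s A, B, C.
#' @export
default_scenarios <- function(delta_mcpr_pp = 10) {
  lapply(c("A", "B", "C"), scenario_spec, delta_mcpr_pp = delta_mcpr_pp)
}

#' Apply a scale-up scenario to baseline covariates
#'
#' Converts the method-mix shares to user-shares of all women (in percentage
#' points of mCPR), adds the whole mCPR increment to the scenario's target
#' class, and re-expresses the mix as shares of the new user base. Existing
#' users do not switch methods, so total modern use is conserved:
#' `mcpr' = mcpr + delta`.
#'
#' @param baseline A list or one-row data frame with `mcpr_pct`,
#'   `pct_permanent`, `pct_larc`.
#' @param scenario A [scenario_spec()].
#' @return Named numeric vector `c(mcpr_pct, pct_permanent, pct_larc)` after
#'   scale-up.
#' @examples
#' apply_scenario(list(mcpr_pct = 33, pct_permanent = 10, pct_larc = 15),
#'                scenario_spec("A"))
#' @export
apply_scenario <- function(baseline, scenario) {
  stopifnot(inherits(scenario, "scenario_spec"))
  m <- baseline$mcpr_pct
  m2 <- m + scenario$delta_mcpr_pp
  if (m2 > 100)
    stop("scenario pushes mCPR above 100% (", m, " + ",
         scenario$delta_mcpr_pp, ")")
  u_perm <- m * baseline$pct_permanent / 100
  u_larc <- m * baseline$pct_larc / 100
  if (scenario$target_class == "permanent") u_perm <- u_perm + scenario$delta_mcpr_pp
  if (scenario$target_class == "larc") u_larc <- u_larc + scenario$delta_mcpr_pp
  c(mcpr_pct = m2,
    pct_permanent = 100 * u_perm / m2,
    pct_larc = 100 * u_larc / m2)
}

#' Predict a renormalized birth-risk distribution
#'
#' Evaluates every category's fitted model at the given covariates, adds the
#' country's empirical-Bayes effect (or a fallback), exponentiates, and
#' rescales within each dimension so the predicted percentages cover 100% of
#' births.
#'
#' @param fits A `birthrisk_fits` object.
#' @param mcpr_pct,pct_permanent,pct_larc Covariates, percent scales.
#' @param country_id Country whose random effect to use (`m3` variant).
#' @param fallback What to do when `country_id` has no estimated effect:
#'   `"zero"` (default), `"regional_average"` (mean effect of the country's
#'   region, requires `region_table`), or `"country"` (error if unknown).
#' @param region_table Data frame `country_id`, `region`; needed for the
#'   regional-average fallback.
#' @param variant Model variant to predict from (default `"m3"`).
#' @return An object of class `prediction_result`: a data frame with columns
#'   `dimension`, `category`, `percent` plus attributes recording the
#'   covariates, country, and random-effect source.
#' @export
predict_distribution <- function(fits, mcpr_pct, pct_permanent, pct_larc,
                                 country_id = NULL,
                                 fallback = c("zero", "regional_average",
                                              "country"),
                                 region_table = NULL, variant = "m3") {
  stopifnot(inherits(fits, "birthrisk_fits"))
  fallback <- match.arg(fallback)
  if (is.null(fits$fits[[variant]]))
    stop("variant ", variant, " was not fitted")
  newdata <- data.frame(mcpr_pct = mcpr_pct, pct_permanent = pct_permanent,
                        pct_larc = pct_larc)
  source_used <- "zero"
  rows <- list()
  for (s in fits$specs) {
    vf <- fits$fits[[variant]][[s$dimension]]
    if (is.null(vf) || !all(s$labels %in% names(vf)))
      stop("missing fitted model for dimension ", s$dimension)
    eta <- vapply(s$labels, function(l) {
      f <- vf[[l]]
      e <- predict(f, newdata = newdata, type = "link", re = "zero")
      b <- 0
      if (!is.null(f$ranef) && !is.null(country_id)) {
        if (country_id %in% names(f$ranef)) {
          b <- f$ranef[[country_id]]
          source_used <<- "country"
        } else if (fallback == "country") {
          stop("unknown country '", country_id,
               "' and fallback = \"country\"")
        } else if (fallback == "regional_average") {
          if (is.null(region_table))
            stop("regional_average fallback needs a region_table")
          reg <- region_table$region[region_table$country_id == country_id]
          if (length(reg) != 1L)
            stop("country '", country_id, "' absent from region_table")
          peers <- region_table$country_id[region_table$region == reg]
          peers <- intersect(peers, names(f$ranef))
          b <- if (length(peers)) mean(f$ranef[peers]) else 0
          source_used <<- "regional_average"
        }
      }
      e + b
    }, numeric(1))
    p <- exp(eta)
    rows[[s$dimension]] <- data.frame(
      dimension = s$dimension, category = s$labels,
      percent = 100 * p / sum(p), row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  structure(out, class = c("prediction_result", "data.frame"),
            covariates = c(mcpr_pct = mcpr_pct, pct_permanent = pct_permanent,
                           pct_larc = pct_larc),
            country_id = if (is.null(country_id)) NA_character_ else country_id,
            random_effect_source = source_used, variant = variant)
}

#' @export
print.prediction_result <- function(x, digits = 2, ...) {
  cat(sprintf("Predicted birth-risk distribution (country: %s, effects: %s)\n",
              attr(x, "country_id"), attr(x, "random_effect_source")))
  cv <- attr(x, "covariates")
  cat(sprintf("  mCPR %.1f%%, permanent %.1f%%, LARC %.1f%% of modern users\n",
              cv["mcpr_pct"], cv["pct_permanent"], cv["pct_larc"]))
  df <- as.data.frame(x)
  df$percent <- round(df$percent, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Run scale-up scenarios for one or more countries
#'
#' For each baseline row, predicts the birth-risk distribution at the
#' baseline covariates and under each scenario's shifted covariates.
#'
#' @param fits A `birthrisk_fits` object.
#' @param baselines Data frame with columns `country_id`, `mcpr_pct`,
#'   `pct_permanent`, `pct_larc` (e.g. each country's most recent survey row).
#' @param scenarios List of [scenario_spec()]s (default the A/B/C set).
#' @inheritParams predict_distribution
#' @return Long data frame with columns `country_id`, `scenario` (`baseline`,
#'   `A`, `B`, `C`), `mcpr_pct`, `dimension`, `category`, `percent`,
#'   `random_effect_source`.
#' @export
run_scenarios <- function(fits, baselines, scenarios = default_scenarios(),
                          fallback = "zero", region_table = NULL,
                          variant = "m3") {
  out <- list()
  for (i in seq_len(nrow(baselines))) {
    base <- baselines[i, , drop = FALSE]
    covsets <- c(list(baseline = c(mcpr_pct = base$mcpr_pct,
                                   pct_permanent = base$pct_permanent,
                                   pct_larc = base$pct_larc)),
                 setNames(lapply(scenarios, apply_scenario, baseline = base),
                          vapply(scenarios, `[[`, "", "label")))
    for (nm in names(covsets)) {
      cv <- covsets[[nm]]
      pr <- predict_distribution(fits, cv["mcpr_pct"], cv["pct_permanent"],
                                 cv["pct_larc"],
                                 country_id = base$country_id,
                                 fallback = fallback,
                                 region_table = region_table,
                                 variant = variant)
      out[[length(out) + 1L]] <- data.frame(
        country_id = base$country_id, scenario = nm,
        mcpr_pct = unname(cv["mcpr_pct"]),
        as.data.frame(pr),
        random_effect_source = attr(pr, "random_effect_source"),
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
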