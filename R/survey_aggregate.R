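#' Restrict births to the pre-survey window
#'
#' Keeps the births that occurred in the `window_months` months up to and
#' including the survey month: those with `survey_cmc - birth_cmc` in
#' `[0, window_months)`. Row order is preserved.
#'
#' @param births Data frame with a `birth_cmc` column (century month code,
#'   months since January 1900).
#' @param survey_cmc Integer survey date in CMC.
#' @param window_months Window length in months (default 36, i.e. 3 years).
#' @return The subset of `births` inside the window.
#' @export
extract_window_births <- function(births, survey_cmc, window_months = 36L) {
  if (window_months < 0) stop("window_months must be nonnegative")
  lag <- survey_cmc - births$birth_cmc
  births[!is.na(lag) & lag >= 0 & lag < window_months, , drop = FALSE]
}

.eligible <- function(women) {
  women$in_union & women$age_years >= 15 & women$age_years <= 49
}

#' Modern contraceptive prevalence (mCPR)
#'
#' Percent of women aged 15-49 in union currently using a modern method. All
#' method codes other than `none` and `traditional` count as modern. Sample
#' weights are honoured; with unit weights this is a simple proportion.
#'
#' @param women Women table (see [validate_women()]).
#' @return mCPR in percent (0-100).
#' @export
compute_mcpr <- function(women) {
  women <- validate_women(women)
  e <- women[.eligible(women), ]
  denom <- sum(e$sample_weight)
  if (nrow(e) == 0L || denom <= 0)
    stop("mCPR undefined: no in-union women aged 15-49")
  num <- sum(e$sample_weight[e$method_code %in% MODERN_CODES])
  100 * num / denom
}

#' Contraceptive method-mix
#'
#' Among modern users (in union, aged 15-49), the percent using permanent
#' methods (female or male sterilization) and the percent using long-acting
#' reversible methods (IUD or implant). The remainder use short-term modern
#' methods (pill, injectable, condom, other).
#'
#' @inheritParams compute_mcpr
#' @return Named numeric vector `c(pct_permanent, pct_larc)`.
#' @export
compute_method_mix <- function(women) {
  women <- validate_women(women)
  e <- women[.eligible(women) & women$method_code %in% MODERN_CODES, ]
  denom <- sum(e$sample_weight)
  if (nrow(e) == 0L || denom <= 0)
    stop("method-mix undefined: no modern contraceptive users")
  c(pct_permanent = 100 * sum(e$sample_weight[e$method_code %in% PERMANENT_CODES]) / denom,
    pct_larc      = 100 * sum(e$sample_weight[e$method_code %in% LARC_CODES]) / denom)
}

#' Birth-risk category percentages
#'
#' For each dimension, the percent of births in each category. Parity and
#' mother's-age percentages are over all births; spacing percentages are over
#' births of order 2 or more (first births have no preceding interval), so
#' each dimension's categories sum to 100. Zero-count categories report 0.
#'
#' @param births Window-filtered births table; a `sample_weight` column is
#'   honoured if present.
#' @param specs Category specifications, as [default_category_specs()].
#' @return Named numeric vector with names `<dimension>__<label>`, or an
#'   all-`NA` vector of the same shape when `births` is empty.
#' @export
compute_category_pct <- function(births, specs = default_category_specs()) {
  labs <- unlist(lapply(specs, function(s)
    paste0(s$dimension, "__", s$labels)), use.names = FALSE)
  if (nrow(births) == 0L)
    return(setNames(rep(NA_real_, length(labs)), labs))
  w <- if (is.null(births$sample_weight)) rep(1, nrow(births)) else births$sample_weight
  cls <- classify_births(births, specs)
  out <- numeric(0)
  for (s in specs) {
    keep <- !is.na(cls[[s$dimension]])
    denom <- sum(w[keep])
    pct <- if (denom > 0) {
      counts <- vapply(s$labels, function(l)
        sum(w[keep][cls[[s$dimension]][keep] == l]), numeric(1))
      100 * counts / denom
    } else rep(NA_real_, length(s$labels))
    out <- c(out, setNames(pct, paste0(s$dimension, "__", s$labels)))
  }
  out[labs]
}

#' Period total fertility rate
#'
#' TFR over the window preceding the survey: 5 times the sum over the seven
#' 5-year age groups 15-19, ..., 45-49 of the group's age-specific fertility
#' rate, births per woman-year. Exposure is reconstructed in completed years
#' from each woman's age at survey: for a 36-month window a woman contributes
#' one woman-year at each of ages `a`, `a-1`, `a-2` (clipped to 15-49).
#' Births are assigned to groups by the mother's completed age at birth.
#'
#' @param women Women table (all surveyed women, any age).
#' @param births Births table (full history; windowing is applied here).
#' @param survey_cmc Survey date in CMC.
#' @param window_months Window length in months, a multiple of 12 (default 36).
#' @return The period TFR (expected births per woman).
#' @export
compute_period_tfr <- function(women, births, survey_cmc, window_months = 36L) {
  if (window_months %% 12 != 0)
    stop("window_months must be a whole number of years")
  women <- validate_women(women)
  yrs <- window_months %/% 12
  breaks <- seq(15, 50, by = 5)
  grp <- function(age) findInterval(age, breaks)  # 1..7 inside 15-49
  expo <- numeric(7)
  for (k in 0:(yrs - 1)) {
    a <- women$age_years - k
    ok <- a >= 15 & a <= 49
    if (any(ok)) {
      g <- grp(a[ok])
      tab <- tapply(women$sample_weight[ok], g, sum)
      expo[as.integer(names(tab))] <- expo[as.integer(names(tab))] + tab
    }
  }
  wb <- extract_window_births(births, survey_cmc, window_months)
  bw <- if (is.null(wb$sample_weight)) rep(1, nrow(wb)) else wb$sample_weight
  bcount <- numeric(7)
  if (nrow(wb) > 0L) {
    a <- wb$mother_age_at_birth_years
    ok <- a >= 15 & a <= 49
    if (any(ok)) {
      tab <- tapply(bw[ok], grp(a[ok]), sum)
      bcount[as.integer(names(tab))] <- tab
    }
  }
  if (any(bcount > 0 & expo == 0))
    stop("TFR undefined: births observed in an age group with zero exposure")
  # expo is in woman-years already (one year per woman per window year)
  asfr <- numeric(7)
  asfr[expo > 0] <- bcount[expo > 0] / expo[expo > 0]
  5 * sum(asfr)
}

#' Aggregate one survey to the unit of analysis
#'
#' Composes windowing, classification, mCPR, method-mix and TFR into a single
#' survey-level row: the covariates and observed category percentages that the
#' log-linear models consume.
#'
#' @param women Women table for one survey.
#' @param births Births table for the same survey (full history).
#' @param survey_id,country_id,year Survey metadata.
#' @param survey_cmc Survey date in CMC.
#' @param window_months Classification window (default 36 months).
#' @param specs Category specifications.
#' @param compute_tfr Also compute the period TFR (default `TRUE`).
#' @return One-row data frame with columns `survey_id`, `country_id`, `year`,
#'   `mcpr_pct`, `pct_permanent`, `pct_larc`, `n_births_window`, `tfr`, and one
#'   `<dimension>__<label>` column per category.
#' @export
aggregate_survey <- function(women, births, survey_id, country_id, year,
                             survey_cmc, window_months = 36L,
                             specs = default_category_specs(),
                             compute_tfr = TRUE) {
  women <- validate_women(women)
  births <- validate_births(births)
  if (nrow(women) == 0L)
    stop("survey ", survey_id, ": no women records")
  if (length(unique(women$survey_id)) > 1L ||
      (nrow(births) > 0L && length(unique(births$survey_id)) > 1L))
    stop("survey ", survey_id, ": records from multiple surveys supplied")
  res <- tryCatch({
    mcpr <- compute_mcpr(women)
    mix <- compute_method_mix(women)
    wb <- extract_window_births(births, survey_cmc, window_months)
    pct <- compute_category_pct(wb, specs)
    tfr <- if (compute_tfr)
      compute_period_tfr(women, births, survey_cmc, window_months)
    else NA_real_
    list(mcpr = mcpr, mix = mix, nwin = nrow(wb), pct = pct, tfr = tfr)
  }, error = function(e)
    stop("survey ", survey_id, ": ", conditionMessage(e), call. = FALSE))
  out <- data.frame(survey_id = survey_id, country_id = country_id,
                    year = year, mcpr_pct = res$mcpr,
                    pct_permanent = unname(res$mix["pct_permanent"]),
                    pct_larc = unname(res$mix["pct_larc"]),
                    n_births_window = res$nwin, tfr = res$tfr,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (nm in names(res$pct)) out[[nm]] <- unname(res$pct[nm])
  out
}

#' Aggregate many surveys
#'
#' Splits the women and births tables by `survey_id`, aggregates each survey
#' with [aggregate_survey()], and binds the rows.
#'
#' @param women,births Individual-level tables covering several surveys.
#' @param survey_meta Data frame with columns `survey_id`, `country_id`,
#'   `year`, `survey_cmc`.
#' @inheritParams aggregate_survey
#' @return Data frame of survey aggregates, one row per survey.
#' @export
aggregate_surveys <- function(women, births, survey_meta, window_months = 36L,
                              specs = default_category_specs(),
                              compute_tfr = TRUE) {
  rows <- lapply(seq_len(nrow(survey_meta)), function(i) {
    sid <- survey_meta$survey_id[i]
    aggregate_survey(women[women$survey_id == sid, , drop = FALSE],
                     births[births$survey_id == sid, , drop = FALSE],
                     survey_id = sid,
                     country_id = survey_meta$country_id[i],
                     year = survey_meta$year[i],
                     survey_cmc = survey_meta$survey_cmc[i],
                     window_months = window_months, specs = specs,
                     compute_tfr = compute_tfr)
  })
  do.call(rbind, rows)
}
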