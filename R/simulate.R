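#' Default generative coefficients for the panel simulator
#'
#' Per-category 4-vectors `(beta0, beta1, beta2, beta3)` on the per-unit
#' percentage-point scale: intercept, mCPR, %permanent, %LARC. mCPR slopes
#' carry the signs and magnitudes typical of the literature (negative for
#' parity 5+, mother's age 35+ and short/medium spacing; positive for first
#' births and 36+-month spacing). Method-mix slopes encode that permanent
#' methods go with relatively more short-spaced and high-parity births.
#' Intercepts are calibrated so that at mCPR 29, 20% permanent and 20% LARC
#' the category means match a typical multi-survey average distribution.
#'
#' @return Data frame with columns `dimension`, `label`, `beta0`..`beta3`.
#' @export
default_truth_betas <- function() {
  b <- data.frame(
    dimension = c(rep("mothers_age", 3), rep("spacing", 4), rep("parity", 3)),
    label = c("<18", "18-34", "35+",
              "<18mo", "18-23mo", "24-35mo", "36+mo",
              "first", "2-4", "5+"),
    # reference mean percents at mcpr 29.2, permanent 20, larc 20
    ref_pct = c(6.5, 80.3, 13.2, 6.0, 9.1, 23.6, 61.3, 26.1, 37.2, 36.6),
    beta1 = c(-0.001, 0.001, -0.006,
              -0.011, -0.010, -0.012, 0.007,
              0.009, 0.006, -0.014),
    beta2 = c(-0.002, 0.000, 0.003,
              0.008, 0.005, 0.002, -0.004,
              -0.004, -0.001, 0.004),
    beta3 = c(-0.001, 0.000, 0.001,
              0.003, 0.002, 0.000, -0.002,
              -0.002, -0.001, 0.002),
    stringsAsFactors = FALSE)
  b$beta0 <- log(b$ref_pct) - b$beta1 * 29.2 - b$beta2 * 20 - b$beta3 * 20
  b[, c("dimension", "label", "beta0", "beta1", "beta2", "beta3")]
}

#' Parameters for the survey-panel generator
#'
#' @param n_countries Number of countries.
#' @param surveys_per_country Single integer or length-2 range; each country
#'   draws its survey count uniformly from the range.
#' @param betas Data frame as [default_truth_betas()].
#' @param tau2 Country random-intercept variance (log scale), default 0.04.
#' @param sigma2 Survey residual variance (log scale), default 0.01.
#' @param mcpr_range mCPR drawn uniformly on this range (percent).
#' @param mix_alpha Dirichlet concentration for the
#'   (permanent, LARC, short-term) composition of modern use.
#' @param year_range Survey years drawn uniformly (integers).
#' @param renormalize If `TRUE`, emitted category percentages are rescaled to
#'   sum to 100 within each dimension. This breaks the exact log-linear data
#'   law (each category is no longer exactly `exp(x'beta + b + e)`) but
#'   matches what observed survey tables look like; default `FALSE`.
#' @param seed Integer seed; all randomness flows from it.
#' @return List of class `panel_params`.
#' @export
panel_params <- function(n_countries = 71, surveys_per_country = c(1, 6),
                         betas = default_truth_betas(), tau2 = 0.04,
                         sigma2 = 0.01, mcpr_range = c(5, 75),
                         mix_alpha = c(permanent = 2, larc = 2, short = 6),
                         year_range = c(1990, 2015), renormalize = FALSE,
                         seed = 1L) {
  stopifnot(tau2 >= 0, sigma2 > 0, n_countries >= 1,
            all(mix_alpha > 0), length(mix_alpha) == 3,
            mcpr_range[1] >= 0, mcpr_range[2] <= 100)
  structure(list(n_countries = n_countries,
                 surveys_per_country = surveys_per_country, betas = betas,
                 tau2 = tau2, sigma2 = sigma2, mcpr_range = mcpr_range,
                 mix_alpha = mix_alpha, year_range = year_range,
                 renormalize = renormalize, seed = as.integer(seed)),
            class = "panel_params")
}

.rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Simulate a survey panel from the log-linear data law
#'
#' Draws, for each survey, covariates (mCPR uniform; method-mix from a
#' Dirichlet composition), a country-level intercept `b_i ~ N(0, tau2)`
#' shared by all of that country's surveys, and an independent survey
#' residual `e ~ N(0, sigma2)` per category, and emits category percent
#' `exp(beta0 + beta1 mcpr + beta2 %permanent + beta3 %larc + b_i + e)`.
#' The generating truth (coefficients, country effects, residual draws) is
#' returned alongside the aggregates so estimators can be checked against it.
#'
#' @param params A [panel_params()] object.
#' @param n_surveys_total Optional exact total number of surveys; when given,
#'   surveys are dealt round-robin so every country has at least one and the
#'   total is exact (e.g. 207 surveys over 71 countries).
#' @return List with `aggregates` (survey-aggregate data frame; the
#'   `n_births_window` column is a nominal constant since no individual
#'   births are simulated) and `truth` (list: `betas`, `country_effects`,
#'   `residuals`, `params`).
#' @export
generate_panel <- function(params, n_surveys_total = NULL) {
  stopifnot(inherits(params, "panel_params"))
  set.seed(params$seed)
  spc <- params$surveys_per_country
  if (!is.null(n_surveys_total)) {
    if (n_surveys_total < params$n_countries)
      stop("need at least one survey per country")
    counts <- rep(n_surveys_total %/% params$n_countries, params$n_countries)
    extra <- n_surveys_total %% params$n_countries
    if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
  } else if (length(spc) == 1L) {
    counts <- rep(spc, params$n_countries)
  } else {
    counts <- sample(seq(spc[1], spc[2]), params$n_countries, replace = TRUE)
  }
  countries <- sprintf("C%03d", seq_len(params$n_countries))
  b_country <- setNames(rnorm(params$n_countries, 0, sqrt(params$tau2)),
                        countries)
  n <- sum(counts)
  country_id <- rep(countries, counts)
  mcpr <- runif(n, params$mcpr_range[1], params$mcpr_range[2])
  mix <- t(vapply(seq_len(n), function(i) .rdirichlet1(params$mix_alpha),
                  numeric(3)))
  pct_perm <- 100 * mix[, 1]; pct_larc <- 100 * mix[, 2]
  year <- sample(seq(params$year_range[1], params$year_range[2]), n,
                 replace = TRUE)
  betas <- params$betas
  eps <- matrix(rnorm(n * nrow(betas), 0, sqrt(params$sigma2)),
                nrow = n, ncol = nrow(betas))
  agg <- data.frame(survey_id = sprintf("S%04d", seq_len(n)),
                    country_id = country_id, year = year,
                    mcpr_pct = mcpr, pct_permanent = pct_perm,
                    pct_larc = pct_larc,
                    n_births_window = 5000L, tfr = NA_real_,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (k in seq_len(nrow(betas))) {
    eta <- betas$beta0[k] + betas$beta1[k] * mcpr +
      betas$beta2[k] * pct_perm + betas$beta3[k] * pct_larc +
      b_country[country_id] + eps[, k]
    agg[[paste0(betas$dimension[k], "__", betas$label[k])]] <- exp(eta)
  }
  if (params$renormalize) {
    for (d in unique(betas$dimension)) {
      cols <- paste0(d, "__", betas$label[betas$dimension == d])
      tot <- rowSums(agg[, cols, drop = FALSE])
      agg[, cols] <- 100 * agg[, cols, drop = FALSE] / tot
    }
  }
  list(aggregates = agg,
       truth = list(betas = betas, country_effects = b_country,
                    residuals = eps, params = params))
}

#' Parameters for the birth-history generator
#'
#' @param n_women Women per survey.
#' @param age_range Completed age at survey drawn uniformly on this range.
#' @param union_prob Probability a woman is in union.
#' @param modern_use_prob Probability an in-union woman aged 15-49 uses a
#'   modern method; this is the generator's implied mCPR / 100.
#' @param traditional_prob Probability such a woman uses a traditional method
#'   (the rest use none).
#' @param method_mix_probs Named probabilities over the eight modern method
#'   codes, conditional on modern use; must sum to 1.
#' @param asfr Length-7 vector of annual age-specific fertility rates for the
#'   groups 15-19 through 45-49. Births arrive as a monthly Bernoulli process
#'   with hazard `asfr/12`, so the implied period TFR is exactly
#'   `5 * sum(asfr)`.
#' @param fixed_interval_months If not `NULL`, after her first birth a woman
#'   bears children at exactly this interval (degenerate-spacing mode for
#'   testing).
#' @param seed Integer seed.
#' @return List of class `history_params`.
#' @export
history_params <- function(n_women = 2000, age_range = c(15, 49),
                           union_prob = 0.7, modern_use_prob = 0.35,
                           traditional_prob = 0.05,
                           method_mix_probs = c(pill = 0.25, injectable = 0.25,
                                                condom = 0.1,
                                                other_modern_short = 0.05,
                                                iud = 0.12, implant = 0.08,
                                                female_sterilization = 0.12,
                                                male_sterilization = 0.03),
                           asfr = c(0.10, 0.20, 0.20, 0.16, 0.10, 0.05, 0.01),
                           fixed_interval_months = NULL, seed = 1L) {
  stopifnot(length(asfr) == 7, all(asfr >= 0),
            abs(sum(method_mix_probs) - 1) < 1e-8,
            all(names(method_mix_probs) %in% MODERN_CODES),
            modern_use_prob + traditional_prob <= 1)
  if (all(asfr == 0) && is.null(fixed_interval_months))
    stop("fertility hazard has zero mass")
  structure(list(n_women = n_women, age_range = age_range,
                 union_prob = union_prob, modern_use_prob = modern_use_prob,
                 traditional_prob = traditional_prob,
                 method_mix_probs = method_mix_probs, asfr = asfr,
                 fixed_interval_months = fixed_interval_months,
                 seed = as.integer(seed)),
            class = "history_params")
}

#' Simulate individual birth histories for one or more surveys
#'
#' Generates women (age, union status, current method, following the stated
#' probabilities) and their dated births. Each woman's fertile months from
#' age 15 to the survey date carry an independent birth probability
#' `asfr[age group]/12`, so group-level ASFRs — and hence the period TFR —
#' have the closed form given in [history_params()]. In degenerate-interval
#' mode, births after the first occur at a fixed spacing instead.
#'
#' @param params A [history_params()] object.
#' @param n_surveys Number of surveys to generate (default 1).
#' @param survey_cmc Survey date(s) in CMC, recycled to `n_surveys`.
#' @param country_ids Country of each survey, recycled.
#' @return List with `women` and `births` data frames in the `women.csv` /
#'   `births.csv` schemas, `survey_meta`, and `truth` (implied mCPR,
#'   method-mix shares, ASFR schedule and TFR).
#' @export
generate_birth_histories <- function(params, n_surveys = 1L,
                                     survey_cmc = 1400L,
                                     country_ids = "C001") {
  stopifnot(inherits(params, "history_params"))
  survey_cmc <- rep_len(survey_cmc, n_surveys)
  country_ids <- rep_len(country_ids, n_surveys)
  women_all <- births_all <- list()
  for (s in seq_len(n_surveys)) {
    # independent deterministic sub-stream per survey
    set.seed(as.integer((as.numeric(params$seed) * 1009 + s) %% 2147483647))
    sid <- sprintf("SV%03d", s)
    nw <- params$n_women
    age <- sample(seq(params$age_range[1], params$age_range[2]), nw,
                  replace = TRUE)
    in_union <- runif(nw) < params$union_prob
    eligible <- in_union & age >= 15 & age <= 49
    u <- runif(nw)
    method <- rep("none", nw)
    modern <- eligible & u < params$modern_use_prob
    trad <- eligible & !modern & u < params$modern_use_prob + params$traditional_prob
    method[trad] <- "traditional"
    method[modern] <- sample(names(params$method_mix_probs), sum(modern),
                             replace = TRUE, prob = params$method_mix_probs)
    woman_id <- sprintf("%s_W%05d", sid, seq_len(nw))
    women_all[[s]] <- data.frame(woman_id = woman_id, survey_id = sid,
                                 age_years = age, in_union = in_union,
                                 method_code = method, sample_weight = 1,
                                 stringsAsFactors = FALSE)
    # month offset of the woman's birthday within the survey year
    offset <- sample(0:11, nw, replace = TRUE)
    born_cmc <- survey_cmc[s] - age * 12L - offset
    h <- params$asfr / 12
    blist <- vector("list", nw)
    for (w in seq_len(nw)) {
      months <- seq(born_cmc[w] + 15L * 12L, survey_cmc[s])
      if (!length(months)) next
      age_m <- (months - born_cmc[w]) %/% 12L
      ok <- age_m >= 15 & age_m <= 49
      months <- months[ok]; age_m <- age_m[ok]
      if (!length(months)) next
      grp <- findInterval(age_m, seq(15, 50, 5))
      if (is.null(params$fixed_interval_months)) {
        hit <- runif(length(months)) < h[grp]
        bm <- months[hit]
      } else {
        hit1 <- which(runif(length(months)) < h[grp])
        bm <- integer(0)
        if (length(hit1)) {
          bm <- months[hit1[1L]]
          while (bm[length(bm)] + params$fixed_interval_months <= survey_cmc[s]) {
            nxt <- bm[length(bm)] + params$fixed_interval_months
            if ((nxt - born_cmc[w]) %/% 12L > 49) break
            bm <- c(bm, nxt)
          }
        }
      }
      if (!length(bm)) next
      ord <- seq_along(bm)
      blist[[w]] <- data.frame(
        woman_id = woman_id[w], survey_id = sid, birth_cmc = bm,
        birth_order = ord,
        preceding_interval_months = c(NA_integer_, diff(bm)),
        mother_age_at_birth_years = (bm - born_cmc[w]) %/% 12L,
        stringsAsFactors = FALSE)
    }
    births_all[[s]] <- do.call(rbind, blist[!vapply(blist, is.null, logical(1))])
  }
  births <- do.call(rbind, births_all[!vapply(births_all, is.null, logical(1))])
  if (is.null(births))
    births <- data.frame(woman_id = character(), survey_id = character(),
                         birth_cmc = integer(), birth_order = integer(),
                         preceding_interval_months = integer(),
                         mother_age_at_birth_years = integer())
  mixp <- params$method_mix_probs
  truth <- list(
    mcpr_pct = 100 * params$modern_use_prob,
    pct_permanent = 100 * sum(mixp[names(mixp) %in% PERMANENT_CODES]),
    pct_larc = 100 * sum(mixp[names(mixp) %in% LARC_CODES]),
    asfr = params$asfr, tfr = 5 * sum(params$asfr), params = params)
  list(women = do.call(rbind, women_all), births = births,
       survey_meta = data.frame(survey_id = sprintf("SV%03d", seq_len(n_surveys)),
                                country_id = country_ids,
                                year = 1900 + survey_cmc %/% 12,
                                survey_cmc = survey_cmc,
                                stringsAsFactors = FALSE),
       truth = truth)
}
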