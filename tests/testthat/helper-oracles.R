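# Independent oracles and small fixture builders shared across tests.

# Brute-force classifier: exhaustive if/else over the stated bounds,
# written independently of the package's interval machinery.
oracle_classify <- function(order, age, interval) {
  parity <- if (order == 1) "first" else if (order <= 4) "2-4" else "5+"
  mothers_age <- if (age <= 17) "<18" else if (age <= 34) "18-34" else "35+"
  spacing <- if (order == 1) NA_character_
  else if (interval < 18) "<18mo"
  else if (interval < 24) "18-23mo"
  else if (interval < 36) "24-35mo"
  else "36+mo"
  list(spacing = spacing, mothers_age = mothers_age, parity = parity)
}

# Direct normal-equations least squares: beta = (X'X)^-1 X'y.
ols_oracle <- function(X, y) drop(solve(crossprod(X), crossprod(X, y)))

# A births table row; interval NA for first births.
birth_row <- function(order, age, interval = NA, cmc = 1400L,
                      woman = "W1", survey = "S1") {
  data.frame(woman_id = woman, survey_id = survey, birth_cmc = cmc,
             birth_order = order,
             preceding_interval_months = interval,
             mother_age_at_birth_years = age, stringsAsFactors = FALSE)
}

# A women table from vectors (recycled).
women_tab <- function(age, union = TRUE, method = "none", weight = 1,
                      survey = "S1") {
  n <- max(length(age), length(union), length(method), length(weight))
  data.frame(woman_id = paste0("W", seq_len(n)), survey_id = survey,
             age_years = rep_len(age, n), in_union = rep_len(union, n),
             method_code = rep_len(method, n),
             sample_weight = rep_len(weight, n), stringsAsFactors = FALSE)
}

# Minimal hand-built risk_loglin object for prediction arithmetic tests.
fake_fit <- function(beta0, beta1 = 0, beta2 = 0, beta3 = 0, ranef = NULL) {
  structure(list(
    coefficients = c(`(Intercept)` = beta0, mcpr_pct = beta1,
                     pct_permanent = beta2, pct_larc = beta3),
    include_method_mix = TRUE, ranef = ranef, variant = "m3",
    tau2 = 0, sigma2 = 1), class = "risk_loglin")
}

# birthrisk_fits container around hand-built per-category fits.
fake_fits <- function(fit_fun, specs = default_category_specs(),
                      variant = "m3") {
  fits <- list()
  fits[[variant]] <- lapply(specs, function(s) {
    out <- lapply(seq_along(s$labels), function(i) fit_fun(s$dimension, i))
    names(out) <- s$labels
    out
  })
  structure(list(fits = fits, specs = specs, variants = variant),
            class = "birthrisk_fits")
}

# Random design rows for regression property tests.
random_design <- function(n, n_countries = max(2L, n %/% 3L), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(y = rnorm(n, 3, 0.5),
             mcpr_pct = runif(n, 5, 75),
             pct_permanent = runif(n, 0, 40),
             pct_larc = runif(n, 0, 40),
             country_id = sample(sprintf("C%02d", seq_len(n_countries)), n,
                                 replace = TRUE),
             survey_id = sprintf("S%03d", seq_len(n)),
             stringsAsFactors = FALSE)
}
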