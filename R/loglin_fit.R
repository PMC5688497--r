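#' Per-category log-linear models of birth risk
#'
#' Fits, for one birth-risk category, the log-linear regression of the
#' category percent on modern contraceptive prevalence and method-mix. Three
#' variants are supported, of increasing structure:
#'
#' * `m1` — ordinary least squares on mCPR alone:
#'   `log(p) = b0 + b1 mCPR`.
#' * `m2` — OLS additionally adjusted for method-mix:
#'   `log(p) = b0 + b1 mCPR + b2 %permanent + b3 %LARC`.
#' * `m3` — the `m2` mean structure plus a country random intercept
#'   `b_i ~ N(0, tau2)` with residual `e ~ N(0, sigma2)`, estimated by
#'   restricted maximum likelihood (REML); country effects are recovered as
#'   empirical-Bayes best linear unbiased predictors (BLUPs).
#'
#' Coefficients are stored per unit percentage point of each covariate; use
#' [report_per10()] for the conventional per-10-point display.
#'
#' @param aggregates Survey-aggregate data frame (see [aggregate_surveys()]).
#' @param dimension,label The risk category to model.
#' @param variant `"m1"`, `"m2"` or `"m3"` (default `"m3"`).
#' @param zero_rule Passed to [build_design()].
#' @return An object of class `risk_loglin`; see Details for components.
#'
#' @details The returned object contains `coefficients`, `se`, `p_value`,
#' `df`, `sigma2` (residual variance), and for `m3` also `tau2` (country
#' variance), `lambda` (`tau2/sigma2`), `ranef` (named BLUP vector) and
#' `reml_logLik`. The design is kept in `$design` so that methods such as
#' [predict.risk_loglin()] and [simulate.risk_loglin()] can reuse it.
#'
#' @seealso [fit_ols()], [fit_hierarchical()], [blup_random_effects()]
#' @examples
#' sim <- generate_panel(panel_params(n_countries = 20, surveys_per_country = 3,
#'                                    seed = 1))
#' fit <- risk_loglin(sim$aggregates, "parity", "5+", variant = "m3")
#' summary(fit)
#' @export
risk_loglin <- function(aggregates, dimension, label,
                        variant = c("m3", "m2", "m1"),
                        zero_rule = "continuity") {
  variant <- match.arg(variant)
  design <- build_design(aggregates, dimension, label, zero_rule)
  fit <- switch(variant,
                m1 = fit_ols(design, include_method_mix = FALSE),
                m2 = fit_ols(design, include_method_mix = TRUE),
                m3 = fit_hierarchical(design, include_method_mix = TRUE))
  fit$dimension <- dimension
  fit$label <- label
  fit$call <- match.call()
  fit
}

# model matrix for a design data frame
.design_matrix <- function(design, include_method_mix) {
  vars <- if (include_method_mix)
    c("mcpr_pct", "pct_permanent", "pct_larc") else "mcpr_pct"
  X <- cbind(`(Intercept)` = 1,
             as.matrix(design[, vars, drop = FALSE]))
  storage.mode(X) <- "double"
  X
}

.check_rank <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    dropped <- colnames(X)[q$pivot[(q$rank + 1L):ncol(X)]]
    stop("rank-deficient design: collinear column(s) ",
         paste(dropped, collapse = ", "))
  }
  invisible(TRUE)
}

#' Ordinary least-squares log-linear fit
#'
#' Fits the log-percent response on mCPR (and optionally method-mix) by
#' classical least squares: residual variance `RSS/(n - p)`, standard errors
#' from the unscaled covariance, and two-sided p-values on `n - p` degrees of
#' freedom.
#'
#' @param design Design rows from [build_design()].
#' @param include_method_mix Include `%permanent` and `%LARC` covariates.
#' @return A `risk_loglin` object with `variant` `"m1"` or `"m2"`.
#' @export
fit_ols <- function(design, include_method_mix = TRUE) {
  X <- .design_matrix(design, include_method_mix)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more surveys (", n, ") than coefficients (", p, ")")
  .check_rank(X)
  fml <- if (include_method_mix)
    y ~ mcpr_pct + pct_permanent + pct_larc else y ~ mcpr_pct
  lmfit <- lm(fml, data = design)
  beta <- coef(lmfit)
  names(beta)[1] <- "(Intercept)"
  df <- n - p
  s2 <- sum(residuals(lmfit)^2) / df
  V <- s2 * chol2inv(qr.R(lmfit$qr))  # classical covariance
  dimnames(V) <- list(names(beta), names(beta))
  se <- sqrt(diag(V))
  tval <- beta / se
  structure(list(
    coefficients = beta, se = se, t_value = tval,
    p_value = 2 * pt(-abs(tval), df), df = df, vcov = V,
    sigma2 = sum(residuals(lmfit)^2) / df, tau2 = NULL, ranef = NULL,
    variant = if (include_method_mix) "m2" else "m1",
    n_surveys = n, n_countries = length(unique(design$country_id)),
    fitted = unname(fitted(lmfit)), residuals = unname(residuals(lmfit)),
    design = design, include_method_mix = include_method_mix
  ), class = "risk_loglin")
}

# Sufficient statistics of the GLS problem at variance ratio lambda.
# V0 = I + lambda * Z Z' is block diagonal by country, so
# V0^-1 = I - (lambda / (1 + n_i lambda)) J within each block.
.gls_at <- function(X, y, country, lambda) {
  n <- nrow(X); p <- ncol(X)
  XtX <- crossprod(X); Xty <- crossprod(X, y); yty <- sum(y * y)
  Sx <- rowsum(X, country); Sy <- rowsum(y, country)
  ni <- as.vector(rowsum(rep(1, n), country))
  w <- lambda / (1 + ni * lambda)
  A <- XtX - crossprod(Sx * sqrt(w))          # X' V0^-1 X
  cvec <- Xty - crossprod(Sx, w * Sy)         # X' V0^-1 y
  q <- yty - sum(w * Sy^2)                    # y' V0^-1 y
  beta <- solve(A, cvec)
  rss <- as.numeric(q - crossprod(cvec, beta))  # r' V0^-1 r at GLS beta
  sigma2 <- rss / (n - p)
  logdetV <- sum(log1p(ni * lambda))
  logdetA <- as.numeric(determinant(A, logarithm = TRUE)$modulus)
  reml <- -0.5 * ((n - p) * (log(2 * pi * sigma2) + 1) + logdetV + logdetA)
  list(beta = drop(beta), A = A, sigma2 = sigma2, reml = reml)
}

#' Restricted log-likelihood profile of the hierarchical fit
#'
#' Evaluates, for a fitted `m3` model, the profiled REML criterion at any
#' variance ratio `lambda = tau2/sigma2`, with the GLS coefficients and
#' residual variance re-profiled at that `lambda`. The fitted `lambda`
#' maximizes this function.
#'
#' @param fit A `risk_loglin` object with `variant == "m3"`.
#' @param lambda Nonnegative variance ratio(s).
#' @return Numeric vector of restricted log-likelihood values.
#' @export
reml_criterion <- function(fit, lambda) {
  stopifnot(inherits(fit, "risk_loglin"), identical(fit$variant, "m3"))
  X <- .design_matrix(fit$design, fit$include_method_mix)
  vapply(lambda, function(l)
    .gls_at(X, fit$design$y, fit$design$country_id, l)$reml, numeric(1))
}

#' Country random-intercept log-linear fit by REML
#'
#' Fits `y = x'beta + b_country + e`, `b ~ N(0, tau2)`, `e ~ N(0, sigma2)`.
#' The variance ratio `lambda = tau2/sigma2` is profiled out: for each
#' `lambda` the coefficients have a closed-form GLS solution and the residual
#' variance a closed-form REML estimate, so estimation reduces to a
#' one-dimensional search. The criterion is scanned on a 50-point log-spaced
#' grid over `lambda` in `[1e-8, 1e3]` plus the boundary `lambda = 0`, then
#' refined with a bounded scalar search; if the boundary is at least as good
#' the model collapses exactly to ordinary least squares (`tau2 = 0`).
#'
#' Wald standard errors come from the GLS covariance at the REML estimates;
#' p-values use a t reference with `n - p - (n_countries - 1)` degrees of
#' freedom (floored at 1) when `tau2 > 0`, and `n - p` at the boundary.
#' Country effects are empirical-Bayes BLUPs (see [blup_random_effects()]).
#'
#' @inheritParams fit_ols
#' @return A `risk_loglin` object with `variant "m3"`.
#' @export
fit_hierarchical <- function(design, include_method_mix = TRUE) {
  X <- .design_matrix(design, include_method_mix)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more surveys (", n, ") than coefficients (", p, ")")
  .check_rank(X)
  country <- design$country_id
  ni <- table(country)
  if (length(ni) < 2L)
    stop("hierarchical model needs surveys from at least 2 countries")
  identifiable <- any(ni >= 2L)
  if (!identifiable)
    warning("no country has repeated surveys; tau2 is not identifiable ",
            "and is fixed at 0")
  y <- design$y
  obj <- function(loglam) .gls_at(X, y, country, exp(loglam))$reml
  lambda_hat <- 0
  if (identifiable) {
    grid <- exp(seq(log(1e-8), log(1e3), length.out = 50L))
    vals <- vapply(grid, function(l) .gls_at(X, y, country, l)$reml, numeric(1))
    i <- which.max(vals)
    lo <- log(grid[max(1L, i - 1L)]); hi <- log(grid[min(50L, i + 1L)])
    opt <- optimize(obj, interval = c(lo, hi), maximum = TRUE, tol = 1e-9)
    lambda_hat <- exp(opt$maximum)
    # boundary check: collapse exactly to lambda = 0 when it does as well
    if (.gls_at(X, y, country, 0)$reml >= opt$objective || lambda_hat <= 2e-8)
      lambda_hat <- 0
  }
  g <- .gls_at(X, y, country, lambda_hat)
  beta <- g$beta
  sigma2 <- g$sigma2
  tau2 <- lambda_hat * sigma2
  V <- sigma2 * solve(g$A)
  dimnames(V) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(V))
  eff_countries <- if (tau2 > 0) length(ni) else 1L
  df <- max(1L, n - p - (eff_countries - 1L))
  tval <- beta / se
  marg_res <- as.vector(y - X %*% beta)
  b <- blup_random_effects(beta, tau2, sigma2, design,
                           include_method_mix = include_method_mix)
  structure(list(
    coefficients = setNames(beta, colnames(X)), se = setNames(se, colnames(X)),
    t_value = tval, p_value = 2 * pt(-abs(tval), df), df = df, vcov = V,
    sigma2 = sigma2, tau2 = tau2, lambda = lambda_hat,
    ranef = b, reml_logLik = g$reml,
    variant = "m3", n_surveys = n, n_countries = length(ni),
    fitted = as.vector(X %*% beta), residuals = marg_res,
    design = design, include_method_mix = include_method_mix
  ), class = "risk_loglin")
}

#' Empirical-Bayes country effects (BLUPs)
#'
#' For country `i` with `n_i` surveys and mean fixed-effect residual
#' `rbar_i`, the best linear unbiased predictor of its random intercept is
#' the shrunken mean `b_i = n_i tau2 / (n_i tau2 + sigma2) * rbar_i`.
#' With `tau2 = 0` every effect is shrunk fully to zero; as `sigma2 -> 0`
#' shrinkage vanishes.
#'
#' @param beta Fixed-effect coefficient vector (intercept first).
#' @param tau2,sigma2 Country and residual variance components.
#' @param design Design rows (see [build_design()]).
#' @param include_method_mix Whether `beta` includes the method-mix terms.
#' @return Named numeric vector of BLUPs, one per country in `design`.
#' @export
blup_random_effects <- function(beta, tau2, sigma2, design,
                                include_method_mix = TRUE) {
  X <- .design_matrix(design, include_method_mix)
  r <- as.vector(design$y - X %*% beta)
  rbar <- tapply(r, design$country_id, mean)
  ni <- as.vector(table(design$country_id)[names(rbar)])
  shrink <- if (tau2 == 0 && sigma2 == 0) rep(0, length(ni))
            else ni * tau2 / (ni * tau2 + sigma2)
  setNames(as.vector(shrink * rbar), names(rbar))
}

#' Per-10-point display of a fitted model
#'
#' Association scales in this literature are conventionally reported per
#' 10-percentage-point change in the covariate; internally coefficients are
#' stored per single point. This helper rescales the slope estimates and
#' standard errors by 10 for display (t statistics and p-values are invariant
#' to the rescaling; the intercept is left alone).
#'
#' @param fit A `risk_loglin` object.
#' @return Data frame with columns `term`, `estimate_per10`, `se_per10`,
#'   `p_value`.
#' @export
report_per10 <- function(fit) {
  stopifnot(inherits(fit, "risk_loglin"))
  sc <- ifelse(names(fit$coefficients) == "(Intercept)", 1, 10)
  data.frame(term = names(fit$coefficients),
             estimate_per10 = unname(fit$coefficients * sc),
             se_per10 = unname(fit$se * sc),
             p_value = unname(fit$p_value),
             row.names = NULL, stringsAsFactors = FALSE)
}
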