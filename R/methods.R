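# S3 methods for risk_loglin objects

#' @export
print.risk_loglin <- function(x, digits = 4, ...) {
  cat(sprintf("Log-linear birth-risk model (%s)%s\n", x$variant,
              if (!is.null(x$dimension))
                sprintf(" for %s '%s'", x$dimension, x$label) else ""))
  cat(sprintf("  %d surveys, %d countries\n", x$n_surveys, x$n_countries))
  cat("Coefficients (per percentage point):\n")
  print(round(x$coefficients, digits))
  if (identical(x$variant, "m3"))
    cat(sprintf("Variance components: tau2 (country) = %.5g, sigma2 (residual) = %.5g\n",
                x$tau2, x$sigma2))
  invisible(x)
}

#' @export
summary.risk_loglin <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `t value` = object$t_value, `Pr(>|t|)` = object$p_value)
  structure(list(fit = object, coefficients = tab,
                 per10 = report_per10(object)),
            class = "summary.risk_loglin")
}

#' @export
print.summary.risk_loglin <- function(x, ...) {
  f <- x$fit
  print.risk_loglin(f)
  cat(sprintf("\nCoefficient tests (t, df = %d):\n", f$df))
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat("\nPer-10-point display:\n")
  print(x$per10, digits = 3)
  if (identical(f$variant, "m3") && length(f$ranef)) {
    cat(sprintf("\nCountry effects (BLUPs): %d countries, range [%.3f, %.3f]\n",
                length(f$ranef), min(f$ranef), max(f$ranef)))
  }
  invisible(x)
}

#' @export
coef.risk_loglin <- function(object, ...) object$coefficients

#' @export
vcov.risk_loglin <- function(object, ...) object$vcov

#' Extract empirical-Bayes country effects
#'
#' @param object A `risk_loglin` fit (variant `"m3"`).
#' @return Named numeric vector of country BLUPs (`NULL` for OLS variants).
#' @export
random_effects <- function(object) {
  stopifnot(inherits(object, "risk_loglin"))
  object$ranef
}

#' Predict from a fitted per-category model
#'
#' Evaluates the linear predictor `x'beta` (plus the country BLUP when a
#' known `country_id` column is supplied and `re = "include"`) at new
#' covariate values, on the log scale or back-transformed to an
#' un-renormalized percent. For renormalized whole-distribution predictions
#' use [predict_distribution()] on a set of category fits.
#'
#' @param object A `risk_loglin` object.
#' @param newdata Data frame with `mcpr_pct` (and `pct_permanent`, `pct_larc`
#'   for `m2`/`m3`); optional `country_id`. Defaults to the training design.
#' @param type `"link"` (log-percent) or `"response"` (percent, not
#'   renormalized).
#' @param re `"include"` (use the country BLUP where available, 0 otherwise)
#'   or `"zero"`.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.risk_loglin <- function(object, newdata = NULL,
                                type = c("link", "response"),
                                re = c("include", "zero"), ...) {
  type <- match.arg(type); re <- match.arg(re)
  if (is.null(newdata)) newdata <- object$design
  X <- .design_matrix(newdata, object$include_method_mix)
  eta <- as.vector(X %*% object$coefficients)
  if (re == "include" && !is.null(object$ranef) &&
      !is.null(newdata$country_id)) {
    b <- object$ranef[as.character(newdata$country_id)]
    b[is.na(b)] <- 0
    eta <- eta + unname(b)
  }
  if (type == "response") exp(eta) else eta
}

#' @export
fitted.risk_loglin <- function(object, ...) object$fitted

#' Residuals of a fitted per-category model
#'
#' @param object A `risk_loglin` object.
#' @param type `"marginal"` (`y - x'beta`, default) or `"conditional"`
#'   (`y - x'beta - b_country`; identical to marginal for OLS variants).
#' @param ... Unused.
#' @return Numeric vector of residuals on the log scale.
#' @export
residuals.risk_loglin <- function(object, type = c("marginal", "conditional"),
                                  ...) {
  type <- match.arg(type)
  r <- object$residuals
  if (type == "conditional" && !is.null(object$ranef))
    r <- r - unname(object$ranef[object$design$country_id])
  r
}

#' Observed versus fitted log-percent
#'
#' @param x A `risk_loglin` object.
#' @param ... Passed to [plot()].
#' @export
plot.risk_loglin <- function(x, ...) {
  obs <- x$design$y
  fit <- predict(x, type = "link")
  plot(fit, obs, xlab = "fitted log-percent", ylab = "observed log-percent",
       main = sprintf("%s '%s' (%s)", x$dimension, x$label, x$variant), ...)
  abline(0, 1, lty = 2)
  invisible(x)
}

#' Simulate responses from a fitted model
#'
#' Draws new log-percent responses at the training design from the fitted
#' model: `x'beta` plus fresh country effects `N(0, tau2)` (for `m3`) and
#' residuals `N(0, sigma2)`.
#'
#' @param object A `risk_loglin` object.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return Data frame with `nsim` columns of simulated `y`.
#' @export
simulate.risk_loglin <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted
  g <- factor(object$design$country_id)
  tau <- sqrt(if (is.null(object$tau2)) 0 else object$tau2)
  out <- replicate(nsim, {
    b <- rnorm(nlevels(g), 0, tau)[as.integer(g)]
    mu + b + rnorm(length(mu), 0, sqrt(object$sigma2))
  })
  as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
}
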