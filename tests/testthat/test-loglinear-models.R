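make_agg <- function(n = 40, seed = 1) {
  generate_panel(panel_params(n_countries = max(2, n %/% 3),
                              surveys_per_country = 3, seed = seed),
                 n_surveys_total = n)$aggregates
}

test_that("design construction logs percents and applies the zero rule", {
  agg <- make_agg(12)
  d <- build_design(agg, "parity", "5+")
  expect_equal(d$y, log(agg$`parity__5+`))
  agg2 <- agg
  agg2$`parity__5+`[1] <- 0
  agg2$n_births_window <- 200L
  d2 <- build_design(agg2, "parity", "5+", zero_rule = "continuity")
  expect_equal(d2$y[1], log(100 * 0.5 / 200))
  expect_equal(nrow(build_design(agg2, "parity", "5+", zero_rule = "drop")),
               nrow(agg2) - 1L)
  expect_error(build_design(agg2, "parity", "5+", zero_rule = "error"),
               "zero percent")
  # surveys with no window births are dropped
  agg3 <- agg
  agg3$n_births_window[2] <- 0L
  agg3$`parity__5+`[2] <- NA
  expect_equal(nrow(build_design(agg3, "parity", "5+")), nrow(agg) - 1L)
  agg4 <- agg; agg4$`parity__5+` <- 0
  expect_error(build_design(agg4, "parity", "5+"), "no nonzero")
})

test_that("OLS recovers a noiseless truth exactly and matches the normal equations", {
  set.seed(3)
  d <- random_design(50)
  beta <- c(2, -0.014, 0.01, 0.005)
  X <- cbind(1, d$mcpr_pct, d$pct_permanent, d$pct_larc)
  d$y <- drop(X %*% beta)
  f <- fit_ols(d, include_method_mix = TRUE)
  expect_equal(unname(coef(f)), beta, tolerance = 1e-10)
  expect_lt(f$sigma2, 1e-20)
  # intercept-only style check: mcpr-only model on centred covariate
  d2 <- random_design(20, seed = 5)
  d2$y <- c(rep(0, 10), rep(2, 10))
  d2$mcpr_pct <- rep(30, 20) + rep(c(-1, 1), 10)
  f2 <- fit_ols(d2, include_method_mix = FALSE)
  expect_equal(unname(coef(f2)[1] + 30 * coef(f2)[2]), 1, tolerance = 1e-10)
  # oracle equivalence on noisy data
  set.seed(9)
  for (i in 1:5) {
    dd <- random_design(30)
    ff <- fit_ols(dd, include_method_mix = TRUE)
    XX <- cbind(1, dd$mcpr_pct, dd$pct_permanent, dd$pct_larc)
    expect_equal(unname(coef(ff)), unname(ols_oracle(XX, dd$y)),
                 tolerance = 1e-8)
  }
})

test_that("OLS inference matches the classical formulas", {
  set.seed(13)
  d <- random_design(35)
  f <- fit_ols(d, include_method_mix = TRUE)
  X <- cbind(1, d$mcpr_pct, d$pct_permanent, d$pct_larc)
  r <- d$y - drop(X %*% coef(f))
  s2 <- sum(r^2) / (35 - 4)
  expect_equal(f$sigma2, s2, tolerance = 1e-10)
  expect_equal(unname(f$se), sqrt(diag(s2 * solve(crossprod(X)))),
               tolerance = 1e-8)
  expect_equal(unname(f$p_value),
               2 * pt(-abs(unname(coef(f)) / unname(f$se)), 31),
               tolerance = 1e-10)
})

test_that("rank-deficient designs fail naming the collinear column", {
  d <- random_design(30, seed = 2)
  d$pct_larc <- 2 * d$pct_permanent
  expect_error(fit_ols(d, TRUE), "collinear.*pct_larc")
})

test_that("REML fit matches lme4 on a simulated panel", {
  skip_if_not_installed("lme4")
  agg <- make_agg(60, seed = 4)
  d <- build_design(agg, "parity", "5+")
  f <- fit_hierarchical(d)
  m <- lme4::lmer(y ~ mcpr_pct + pct_permanent + pct_larc + (1 | country_id),
                  data = d, REML = TRUE)
  expect_equal(unname(coef(f)), unname(lme4::fixef(m)), tolerance = 1e-6)
  vc <- as.data.frame(lme4::VarCorr(m))
  expect_equal(f$tau2, vc$vcov[1], tolerance = 1e-5)
  expect_equal(f$sigma2, vc$vcov[2], tolerance = 1e-5)
  re <- lme4::ranef(m)$country_id
  expect_equal(unname(f$ranef[rownames(re)]), re[, 1], tolerance = 1e-5)
})

test_that("the returned REML criterion beats a grid over the variance ratio", {
  agg <- make_agg(45, seed = 6)
  f <- risk_loglin(agg, "spacing", "36+mo", variant = "m3")
  grid <- seq(0, 20, length.out = 50)
  vals <- reml_criterion(f, grid)
  expect_true(all(f$reml_logLik >= vals - 1e-8))
})

test_that("REML is invariant to country relabeling and row order", {
  agg <- make_agg(36, seed = 8)
  d <- build_design(agg, "mothers_age", "35+")
  f1 <- fit_hierarchical(d)
  perm <- sample(nrow(d))
  d2 <- d[perm, ]
  map <- setNames(sprintf("Z%02d", seq_along(unique(d$country_id))),
                  sort(unique(d$country_id)))
  d2$country_id <- unname(map[d2$country_id])
  f2 <- fit_hierarchical(d2)
  # agreement up to the optimizer's tolerance on the variance ratio
  expect_equal(coef(f1), coef(f2), tolerance = 1e-6)
  expect_equal(f1$tau2, f2$tau2, tolerance = 1e-5)
  expect_equal(unname(f1$ranef), unname(f2$ranef[map[names(f1$ranef)]]),
               tolerance = 1e-5)
})

test_that("with one survey per country the hierarchical fit collapses to OLS", {
  set.seed(15)
  d <- random_design(30, n_countries = 30)
  d$country_id <- sprintf("C%02d", 1:30)
  expect_warning(f3 <- fit_hierarchical(d), "not identifiable")
  f2 <- fit_ols(d, include_method_mix = TRUE)
  expect_equal(f3$tau2, 0)
  expect_equal(coef(f3), coef(f2), tolerance = 1e-8)
  expect_true(all(f3$ranef == 0))
})

test_that("t statistics are invariant under affine covariate rescaling", {
  agg <- make_agg(40, seed = 10)
  d <- build_design(agg, "parity", "first")
  f1 <- fit_hierarchical(d)
  d2 <- d
  d2$mcpr_pct <- d$mcpr_pct / 10  # per-10-point coding
  f2 <- fit_hierarchical(d2)
  expect_equal(unname(coef(f2)["mcpr_pct"]),
               unname(coef(f1)["mcpr_pct"]) * 10, tolerance = 1e-6)
  expect_equal(f1$p_value, f2$p_value, tolerance = 1e-6)
})

test_that("BLUPs follow the shrinkage formula including its limits", {
  # residuals are the response itself when beta = 0
  d <- data.frame(y = c(1, 1, 1, 1, 4, -2),
                  mcpr_pct = 0, pct_permanent = 0, pct_larc = 0,
                  country_id = c(rep("A", 4), "B", "C"),
                  survey_id = paste0("S", 1:6))
  beta <- c(0, 0, 0, 0)
  # n_A = 4, tau2 = sigma2 -> shrinkage 4/5
  b <- blup_random_effects(beta, 1, 1, d)
  expect_equal(b[["A"]], 0.8 * 1, tolerance = 1e-12)
  expect_equal(b[["B"]], 0.5 * 4, tolerance = 1e-12)
  # full shrinkage at tau2 = 0
  expect_true(all(blup_random_effects(beta, 0, 1, d) == 0))
  # no shrinkage as sigma2 -> 0
  b0 <- blup_random_effects(beta, 1, 1e-12, d)
  expect_equal(b0[["B"]], 4, tolerance = 1e-6)
  # |b| grows with n_i for fixed mean residual and components
  shrink <- function(ni) ni * 0.04 / (ni * 0.04 + 0.01)
  expect_true(all(diff(shrink(1:10)) > 0))
})

test_that("per-10 display rescales estimates and SEs but not p-values", {
  agg <- make_agg(30, seed = 12)
  f <- risk_loglin(agg, "parity", "5+", variant = "m2")
  tab <- report_per10(f)
  expect_equal(tab$estimate_per10[tab$term == "mcpr_pct"],
               unname(coef(f)["mcpr_pct"]) * 10)
  expect_equal(tab$se_per10[tab$term == "mcpr_pct"],
               unname(f$se["mcpr_pct"]) * 10)
  expect_equal(tab$p_value, unname(f$p_value))
  expect_equal(tab$estimate_per10[tab$term == "(Intercept)"],
               unname(coef(f)[1]))
})

test_that("model methods behave coherently", {
  agg <- make_agg(36, seed = 14)
  f <- risk_loglin(agg, "spacing", "<18mo", variant = "m3")
  expect_output(print(f), "m3")
  expect_output(print(summary(f)), "Per-10")
  expect_equal(length(residuals(f)), f$n_surveys)
  expect_equal(residuals(f), f$design$y - fitted(f))
  cond <- residuals(f, type = "conditional")
  expect_lte(sum(cond^2), sum(residuals(f)^2) + 1e-12)
  expect_equal(dim(vcov(f)), c(4L, 4L))
  s <- simulate(f, nsim = 3, seed = 1)
  expect_equal(dim(s), c(f$n_surveys, 3L))
  expect_identical(s, simulate(f, nsim = 3, seed = 1))
  p <- predict(f, type = "response")
  expect_true(all(p > 0))
})
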