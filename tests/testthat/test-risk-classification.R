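test_that("births are classified by the stated half-open bounds", {
  expect_equal(classify_birth(birth_row(5, 17, 12)),
               list(spacing = "<18mo", mothers_age = "<18", parity = "5+"))
  expect_equal(classify_birth(birth_row(1, 25)),
               list(spacing = NA_character_, mothers_age = "18-34",
                    parity = "first"))
  # boundary case: 24 months falls in 24-35, age 35 in 35+
  expect_equal(classify_birth(birth_row(2, 35, 24)),
               list(spacing = "24-35mo", mothers_age = "35+", parity = "2-4"))
  # remaining boundary months/ages under the half-open convention
  expect_equal(classify_birth(birth_row(2, 18, 18))$spacing, "18-23mo")
  expect_equal(classify_birth(birth_row(2, 18, 18))$mothers_age, "18-34")
  expect_equal(classify_birth(birth_row(4, 34, 36))$spacing, "36+mo")
  expect_equal(classify_birth(birth_row(4, 34, 36))$parity, "2-4")
  expect_equal(classify_birth(birth_row(5, 17, 17))$spacing, "<18mo")
})

test_that("invalid birth records are rejected with the field named", {
  expect_error(classify_birth(birth_row(1, 25, 20)),
               "preceding_interval_months.*first")
  expect_error(classify_birth(birth_row(2, 25)),
               "preceding_interval_months.*absent")
  expect_error(classify_birth(birth_row(0, 25)), "birth_order")
  b <- rbind(birth_row(1, 20, cmc = 1400L), birth_row(2, 22, 12, cmc = 1390L))
  expect_error(validate_births(b), "birth_cmc")
})

test_that("classification agrees with the brute-force oracle on random births", {
  set.seed(42)
  n <- 10000
  order <- sample(1:9, n, replace = TRUE)
  age <- sample(12:49, n, replace = TRUE)
  interval <- ifelse(order == 1, NA, sample(1:80, n, replace = TRUE))
  # force coverage of the boundary values
  order[1:8] <- 2
  interval[1:8] <- c(17, 18, 23, 24, 35, 36, 37, 18)
  age[1:8] <- c(17, 18, 34, 35, 17, 18, 34, 35)
  births <- data.frame(birth_order = order,
                       preceding_interval_months = interval,
                       mother_age_at_birth_years = age)
  got <- classify_births(births)
  want <- t(mapply(function(o, a, i) unlist(oracle_classify(o, a, i)),
                   order, age, ifelse(is.na(interval), -1, interval)))
  want[order == 1, "spacing"] <- NA
  expect_identical(got$parity, unname(want[, "parity"]))
  expect_identical(got$mothers_age, unname(want[, "mothers_age"]))
  expect_identical(got$spacing, unname(want[, "spacing"]))
})

test_that("window extraction keeps exactly the births within the window", {
  b <- do.call(rbind, list(birth_row(1, 20, cmc = 1160L),
                           birth_row(2, 21, 10, cmc = 1170L),
                           birth_row(3, 23, 30, cmc = 1190L)))
  expect_equal(nrow(extract_window_births(b, 1195L, 36L)), 3L)
  b2 <- rbind(birth_row(1, 20, cmc = 1100L), birth_row(2, 27, 90, cmc = 1190L))
  kept <- extract_window_births(b2, 1195L)
  expect_equal(kept$birth_cmc, 1190L)
  expect_equal(nrow(extract_window_births(b[0, ], 1195L)), 0L)
  expect_error(extract_window_births(b, 1195L, -1L), "nonnegative")
  # two ways of counting agree on random data
  set.seed(7)
  cmc <- sample(1200:1500, 500, replace = TRUE)
  bb <- birth_row(1, 20)[rep(1, 500), ]
  bb$birth_cmc <- cmc
  expect_equal(nrow(extract_window_births(bb, 1450L, 36L)),
               sum(1450L - cmc >= 0 & 1450L - cmc < 36L))
})

test_that("mCPR uses in-union women 15-49 and modern methods only", {
  w <- women_tab(25, union = TRUE, method = c("pill", "none", "none", "none"))
  expect_equal(compute_mcpr(w), 25)
  expect_error(compute_mcpr(women_tab(25, union = FALSE, method = "pill")),
               "no in-union women")
  expect_equal(compute_mcpr(women_tab(25, method = c("traditional", "none"))), 0)
  # out-of-range ages excluded from the denominator
  w2 <- women_tab(c(25, 25, 14, 52), method = c("iud", "none", "pill", "pill"))
  expect_equal(compute_mcpr(w2), 50)
})

test_that("method-mix shares are among modern users", {
  w <- women_tab(30, method = c(rep("female_sterilization", 2), rep("iud", 3),
                                rep("pill", 5)))
  expect_equal(compute_method_mix(w),
               c(pct_permanent = 20, pct_larc = 30))
  expect_equal(compute_method_mix(women_tab(30, method = "injectable")),
               c(pct_permanent = 0, pct_larc = 0))
  expect_error(compute_method_mix(women_tab(30, method = "none")),
               "no modern")
})

test_that("category percentages use the right denominators and sum to 100", {
  b <- rbind(birth_row(1, 20), birth_row(2, 22, 10), birth_row(2, 24, 20),
             birth_row(5, 30, 40))
  pct <- compute_category_pct(b)
  expect_equal(unname(pct[c("parity__first", "parity__2-4", "parity__5+")]),
               c(25, 50, 25))
  expect_equal(unname(pct["spacing__24-35mo"]), 0)
  expect_equal(unname(pct[c("spacing__<18mo", "spacing__18-23mo",
                            "spacing__36+mo")]),
               rep(100 / 3, 3))
  for (d in c("spacing", "mothers_age", "parity"))
    expect_equal(sum(pct[grep(paste0("^", d, "__"), names(pct))]), 100,
                 tolerance = 1e-12)
  expect_true(all(is.na(compute_category_pct(b[0, ]))))
})

test_that("weighted aggregation with equal weights reproduces unweighted", {
  set.seed(11)
  hp <- history_params(n_women = 300, seed = 3)
  sim <- generate_birth_histories(hp, survey_cmc = 1400L)
  w2 <- sim$women; w2$sample_weight <- 2.5
  b2 <- sim$births; b2$sample_weight <- 2.5
  a1 <- aggregate_survey(sim$women, sim$births, "S", "C", 2016, 1400L)
  a2 <- aggregate_survey(w2, b2, "S", "C", 2016, 1400L)
  num <- vapply(a1, is.numeric, logical(1))
  expect_equal(a1[, num], a2[, num], tolerance = 1e-12)
})

test_that("period TFR matches its definition on a constructed cohort", {
  # 5 women per single age 15..51: exposure at ages a, a-1, a-2 clipped to
  # 15-49 gives every 5-year group exactly 75 woman-years; one birth per
  # group makes each ASFR 1/75 and TFR = 5 * 7/75
  women <- women_tab(rep(15:51, each = 5))
  women$woman_id <- paste0("W", seq_len(nrow(women)))
  births <- do.call(rbind, lapply(seq(17, 47, by = 5), function(a)
    birth_row(1, a, cmc = 1395L, woman = paste0("B", a))))
  births$survey_id <- "S1"
  got <- compute_period_tfr(women, births, 1400L, 36L)
  # exposure per group: 15 woman-years (5 women x 3 years, ages align)
  expect_equal(got, 5 * 7 * (1 / (15 * 5)))
  # no births -> zero
  expect_equal(compute_period_tfr(women, births[0, ], 1400L), 0)
})

test_that("survey aggregation composes the pieces and checks its invariants", {
  women <- women_tab(c(20, 25, 30, 35, 40),
                     method = c("pill", "iud", "none", "female_sterilization",
                                "traditional"))
  births <- rbind(birth_row(1, 19, cmc = 1390L, woman = "W1"),
                  birth_row(2, 21, 20, cmc = 1395L, woman = "W1"),
                  birth_row(1, 34, cmc = 1399L, woman = "W4"))
  agg <- aggregate_survey(women, births, "S1", "C1", 2016, 1400L)
  expect_equal(agg$mcpr_pct, 60)  # 3 modern of 5 in-union 15-49
  expect_equal(agg$pct_permanent, 100 / 3)
  expect_equal(agg$pct_larc, 100 / 3)
  expect_equal(agg$n_births_window, 3L)
  expect_equal(agg$`parity__first`, 200 / 3)
  expect_equal(agg$`spacing__18-23mo`, 100)
  expect_true(agg$pct_permanent + agg$pct_larc <= 100)
  expect_error(aggregate_survey(women[0, ], births, "S1", "C1", 2016, 1400L),
               "S1")
})
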