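make_level_table <- function(n_duos = 6, level_means = c(5, 4, 3, 2, 1),
                             sd = 0.5, duo_sd = 0, seed = 1) {
  lvls <- c("half_bar", "one_bar", "two_bars", "three_bars", "four_bars")
  set.seed(seed)
  duo_eff <- rnorm(n_duos, sd = duo_sd)
  do.call(rbind, lapply(seq_len(n_duos), function(d)
    data.frame(duo_id = sprintf("duo%02d", d), level = lvls,
               mean_power = level_means + duo_eff[d] + rnorm(5, sd = sd))))
}

test_that("a zero response yields zero coefficients and zero R-squared", {
  tab <- make_level_table()
  tab$mean_power <- 0
  fit <- fit_model(model_spec("mean_power", "level",
                              baselines = list(level = "four_bars")), tab)
  expect_true(all(abs(fit$coefficients$estimate) < 1e-12))
  expect_equal(fit$r2_marginal, 0)
  expect_equal(fit$r2_conditional, 0)
})

test_that("nested shorthand expands as main effect plus interaction-within", {
  tab <- make_level_table()
  tab$take <- rep(c("0", "2"), length.out = nrow(tab))
  fit <- fit_model(model_spec("mean_power", "level/take",
                              baselines = list(level = "four_bars",
                                               take = "0")), tab)
  trms <- fit$coefficients$term
  expect_true(any(grepl("^level", trms) & !grepl(":", trms)))
  expect_true(any(grepl("level.*:take", trms)))
})

test_that("negligible between-duo variance triggers the flagged OLS fallback", {
  tab <- make_level_table(duo_sd = 0)
  fit <- fit_model(model_spec("mean_power", "level",
                              random_intercept = "duo_id",
                              baselines = list(level = "four_bars")), tab)
  expect_true(fit$fallback)
  expect_equal(fit$engine, "lm")
  # the fallback reproduces the pure OLS fixed effects exactly
  ols <- fit_model(model_spec("mean_power", "level",
                              baselines = list(level = "four_bars")), tab)
  expect_equal(fit$coefficients$estimate, ols$coefficients$estimate,
               tolerance = 1e-12)
})

test_that("a real random intercept is kept and shows up in conditional R2", {
  tab <- make_level_table(n_duos = 12, duo_sd = 3, sd = 0.3, seed = 4)
  fit <- fit_model(model_spec("mean_power", "level",
                              random_intercept = "duo_id",
                              baselines = list(level = "four_bars")), tab)
  expect_false(fit$fallback)
  expect_equal(fit$engine, "lmer")
  expect_gt(fit$r2_conditional, fit$r2_marginal)
  # every CI brackets its estimate
  expect_true(all(fit$coefficients$ci_lo <= fit$coefficients$estimate &
                    fit$coefficients$estimate <= fit$coefficients$ci_hi))
})

test_that("planted EPT-leadership slope is recovered from cohort ground truth", {
  spec <- cohort_spec(n_duos = 24, lead_slope = 0.02, noise_sd = 1, seed = 11)
  cohort <- simulate_cohort(spec, piece_template(n_bars = 24, fs = 24))
  truth <- cohort$truth
  truth$phase_ms <- 1000 * truth$lag_s  # exact measurement stand-in
  truth$pianist_ept <- truth$pianist_ept
  fit <- fit_model(model_spec("phase_ms", c("pianist_ept", "singer_ept")),
                   truth)
  co <- fit$coefficients[fit$coefficients$term == "singer_ept", ]
  expect_equal(co$estimate, -20, tolerance = 1e-9)  # -1000 * lead_slope
  expect_true(co$ci_hi < 0)
})

test_that("rank-deficient designs are rejected with the aliased terms", {
  tab <- make_level_table()
  tab$dup <- tab$level
  expect_error(fit_model(model_spec("mean_power", c("level", "dup"),
                                    baselines = list(level = "four_bars",
                                                     dup = "four_bars")), tab),
               "aliased")
})

test_that("Tukey contrasts: identical groups, separated groups, count", {
  set.seed(9)
  same <- data.frame(g = rep(c("a", "b"), each = 20),
                     y = rep(rnorm(20), 2))
  fit_same <- fit_model(model_spec("y", "g", baselines = list(g = "a")), same)
  ct <- tukey_contrasts(fit_same, "g")
  expect_equal(ct$p_value, 1, tolerance = 1e-6)

  sep <- data.frame(g = rep(c("a", "b"), each = 20),
                    y = c(rnorm(20), rnorm(20) + 50))
  fit_sep <- fit_model(model_spec("y", "g", baselines = list(g = "a")), sep)
  expect_lt(tukey_contrasts(fit_sep, "g")$p_value, 0.001)

  tab <- make_level_table()
  fit5 <- fit_model(model_spec("mean_power", "level",
                               baselines = list(level = "four_bars")), tab)
  expect_equal(nrow(tukey_contrasts(fit5, "level")), choose(5, 2))

  expect_error(tukey_contrasts(fit_same, "missing_factor"), "not in the model")
})

test_that("Bonferroni threshold is alpha over m", {
  expect_equal(bonferroni_threshold(0.05, 24), 0.05 / 24)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 4), 0.0025)
  expect_error(bonferroni_threshold(1.2, 3), "probability")
  expect_error(bonferroni_threshold(0.05, 0), "integer")
})
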