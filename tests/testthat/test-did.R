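test_that("equal trends in both countries give a null interaction", {
  # saturated fit on large aggregated arms with identical trends
  n <- c(20000, 20000, 40000, 40000)
  y <- round(n * c(0.10, 0.12, 0.10, 0.12))
  r <- did_effect_counts(y, n)
  expect_lt(r$ci_low, 1)
  expect_gt(r$ci_high, 1)
  expect_lt(abs(log(r$or)), 0.1)
})

test_that("reconstructed DUIC-sample counts reproduce the ratio of odds ratios", {
  # cases implied by printed prevalences 28.5/26.8/12.8/16.3% of 393/589/86/92
  trials <- c(86, 92, 393, 589)
  cases <- round(trials * c(0.128, 0.163, 0.285, 0.268))
  expect_identical(cases, c(11, 15, 112, 158))
  r <- did_effect_counts(cases, trials)
  oracle <- ((158 / 431) / (112 / 281)) / ((15 / 77) / (11 / 75))
  expect_equal(r$or, oracle, tolerance = 1e-8)
  expect_equal(round(r$or, 3), 0.692)
})

test_that("weighted cell prevalences give an interaction OR near 1.19", {
  trials <- c(2132, 2102, 6670, 9692)
  prev <- c(0.094, 0.096, 0.121, 0.144)
  r <- did_effect(data.frame(
    country = rep(c("control", "intervention"), each = 2),
    wave = rep(c("t0", "t1"), 2), y = prev), "y", weights = trials)
  oracle <- exp((qlogis(0.144) - qlogis(0.121)) -
                  (qlogis(0.096) - qlogis(0.094)))
  expect_equal(r$or, oracle, tolerance = 1e-8)
  # consistent with the weighted-model headline estimate up to rounding of
  # the printed prevalences
  expect_lt(abs(r$or - 1.18), 0.05)
})

test_that("covariate screening keeps associated and drops independent covariates", {
  set.seed(71)
  n <- 2500
  d <- data.frame(y = rbinom(n, 1, 0.2))
  d$same <- factor(ifelse(d$y == 1, "a", "b"))
  d$noise <- factor(sample(c("u", "v", "w"), n, TRUE))
  sc <- screen_covariates(d, "y", c("same", "noise"))
  expect_true(sc$selected[sc$covariate == "same"])
  expect_lt(sc$p_value[sc$covariate == "same"], 1e-10)
  # under independence the exclusion rate is 1 - alpha = 0.90
  excl <- replicate(200, {
    dd <- data.frame(y = rbinom(800, 1, 0.2),
                     x = factor(sample(c("u", "v"), 800, TRUE)))
    !screen_covariates(dd, "y", "x")$selected
  })
  expect_gt(mean(excl), 0.85)
  # degenerate inputs
  expect_identical(nrow(screen_covariates(d, "y", character(0))), 0L)
  d$flat <- factor("only")
  expect_warning(sc2 <- screen_covariates(d, "y", "flat"), "single level")
  expect_identical(nrow(sc2), 0L)
})

test_that("baseline subgroup imputation follows rate and mode contracts", {
  d <- data.frame(id = sprintf("x%02d", 1:10), wave = "t0",
                  cannabis_freq = "less_than_monthly", duic_12m = NA)
  z <- impute_subgroup(d, 0)
  expect_false(any(z$duic_12m))
  z2 <- impute_subgroup(d, 0.25)
  expect_true(sum(z2$duic_12m) %in% c(2L, 3L))
  expect_identical(attr(z2, "imputation")$mode, "deterministic")
  s1 <- impute_subgroup(d, 0.4, mode = "stochastic", seed = 5)
  s2 <- impute_subgroup(d, 0.4, mode = "stochastic", seed = 5)
  expect_identical(s1$duic_12m, s2$duic_12m)
  d2 <- d; d2$cannabis_freq <- "daily"
  expect_warning(impute_subgroup(d2, 0.4), "empty")
})

test_that("bootstrap prevalence intervals are seeded percentile intervals", {
  x0 <- rep(0, 50)
  ci0 <- bootstrap_prevalence(x0, B = 200, seed = 1)
  expect_identical(c(ci0$ci_low, ci0$ci_high), c(0, 0))
  set.seed(2)
  x <- rbinom(400, 1, 0.3)
  a <- bootstrap_prevalence(x, B = 500, seed = 9)
  b <- bootstrap_prevalence(x, B = 500, seed = 9)
  expect_identical(a, b)
  expect_lt(a$ci_low, a$estimate)
  expect_gt(a$ci_high, a$estimate)
  # stratified resampling returns one row per stratum
  st <- rep(c("control_t0", "control_t1"), each = 200)
  s <- bootstrap_prevalence(x, strata = st, B = 300, seed = 4)
  expect_identical(s$stratum, c("control_t0", "control_t1"))
  expect_equal(s$estimate[1], mean(x[1:200]))
})

test_that("a generated social-desirability effect is recovered by the model", {
  # the generator ties DUIC to the NQ- score with a per-SD odds ratio of 0.6;
  # an ordinary model spec with nq_minus as covariate must recover it
  cfg <- generator_config(
    n = c(control_t0 = 4000, control_t1 = 4000,
          intervention_t0 = 8000, intervention_t1 = 8000),
    p_use = c(control_t0 = 0.3, control_t1 = 0.3, intervention_t0 = 0.3),
    or_did = 1, seed = 3131)
  tab <- recode_covariates(generate_survey(cfg), seed = 1)
  s2 <- derive_samples(tab)$sample2$data
  r <- did_effect(s2, "duic_12m", covariates = "nq_minus")
  nq <- r$table[r$table$term == "nq_minus", ]
  expect_lt(nq$or, 1)
  expect_lt(abs(nq$estimate - log(0.6)), 3 * nq$se)
})

test_that("a negative-control outcome yields a non-significant interaction", {
  # outcome independent of country and wave by construction
  set.seed(88)
  sig <- replicate(120, {
    n <- c(500, 500, 1000, 1000)
    y <- rbinom(4, n, 0.35)
    did_effect_counts(y, n)$p_value < 0.05
  })
  expect_gte(mean(!sig), 0.93 - 3 * sqrt(0.05 * 0.95 / 120))
})
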