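test_that("a clean table passes the quality filters untouched", {
  cfg <- small_config()
  tab <- generate_survey(cfg)
  fl <- apply_quality_filters(tab)
  expect_identical(nrow(fl$data), nrow(tab))
  expect_identical(sum(fl$log$removed), 0L)
})

test_that("planted artifacts are removed and attributed to the right filter", {
  cfg <- small_config(artifact_rates = c(speeder = 0.02, straightliner = 0.01,
                                         control_fail = 0.01,
                                         duplicate = 0.01))
  tab <- inject_artifacts(generate_survey(cfg), cfg)
  led <- planted_ledger(tab)
  fl <- apply_quality_filters(tab)
  n <- nrow(tab)
  # per-filter counts: duplicates remove both wave rows of each planted id
  lg <- fl$log
  expect_identical(lg$removed[lg$filter == "duplicate"],
                   2L * sum(led$artifact == "duplicate"))
  for (f in c("speeder", "straightliner"))
    expect_identical(lg$removed[lg$filter == f],
                     as.integer(sum(led$artifact == f)))
  expect_identical(lg$removed[lg$filter == "control_check"],
                   as.integer(sum(led$artifact == "control_fail")))
  # the removed id set is exactly the planted truth
  expect_setequal(fl$removed$id, led$id)
  # duplicate ids are gone from both waves
  dup <- led$id[led$artifact == "duplicate"]
  expect_false(any(fl$data$id %in% dup))
  # log reconciles sequentially
  expect_identical(lg$before - lg$removed, c(lg$before[-1],
                                             nrow(fl$data)))
})

test_that("filter attribution is stable under row permutation", {
  cfg <- small_config(artifact_rates = c(speeder = 0.02, straightliner = 0.01,
                                         control_fail = 0.01,
                                         duplicate = 0.01), seed = 55)
  tab <- inject_artifacts(generate_survey(cfg), cfg)
  lg1 <- apply_quality_filters(tab)$log
  set.seed(1)
  lg2 <- apply_quality_filters(tab[sample(nrow(tab)), ])$log
  expect_identical(lg1$removed, lg2$removed)
})

test_that("response metrics reproduce the survey funnel arithmetic", {
  rm1 <- response_metrics(127552, 30650, 13593)
  expect_identical(rm1$rate_pct[rm1$metric == "completion_rate"], 44.3)
  rm2 <- response_metrics(500, 500, 500)
  expect_identical(rm2$rate_pct, c(100, 100))
  rm3 <- response_metrics(100, 40, 10)
  expect_identical(rm3$rate_pct, c(40, 25))
  expect_error(response_metrics(0, 0, 0), class =
                 "cannadid_degenerate_rate_error")
  expect_error(response_metrics(10, 20, 5), class = "cannadid_config_error")
})

test_that("analytic samples implement the inclusion rules", {
  cfg <- small_config(p_use = c(control_t0 = 0.3, control_t1 = 0.3,
                                intervention_t0 = 0.3),
                      p_medical_rx = 0.15, seed = 91)
  clean <- recode_covariates(generate_survey(cfg), seed = 1)
  ss <- derive_samples(clean)
  expect_identical(nrow(ss$sample1$data), nrow(clean))
  d2 <- ss$sample2$data
  expect_true(all(d2$cannabis_freq %in% c("monthly", "weekly", "daily")))
  expect_false(any(d2$medical_only_rx))
  # medical daily users exist in the table but never in Samples 2 or 3
  med_daily <- clean$id[clean$medical_only_rx &
                          clean$cannabis_freq == "daily"]
  expect_gt(length(med_daily), 0)
  expect_false(any(med_daily %in% d2$id))
  expect_false(any(med_daily %in% ss$sample3$data$id))
  # less-than-monthly users excluded from Sample 2 at either wave
  expect_false(any(ss$sample2$data$cannabis_freq == "less_than_monthly"))
  d3 <- ss$sample3$data
  expect_true(all(d3$cannabis_12m & d3$duic_30d & !d3$medical_only_rx))
  expect_false(any(is.na(d3$duic_count_category)))
  expect_false(any(is.na(d3$couse_category)))
  # derivation logs reconcile
  for (s in ss) {
    lg <- s$derivation_log
    expect_identical(lg$before[-1], (lg$before - lg$removed)[-nrow(lg)])
    expect_identical(lg$before[nrow(lg)] - lg$removed[nrow(lg)],
                     nrow(s$data))
  }
})

test_that("a table without cannabis users yields empty Samples 2 and 3", {
  cfg <- small_config(p_use = c(control_t0 = 0, control_t1 = 0,
                                intervention_t0 = 0))
  clean <- generate_survey(cfg)
  ss <- derive_samples(clean)
  expect_identical(nrow(ss$sample2$data), 0L)
  expect_identical(nrow(ss$sample3$data), 0L)
  expect_identical(nrow(ss$sample1$data), nrow(clean))
})

test_that("non-binary respondents are reassigned by a seeded fair coin", {
  tab <- data.frame(id = as.character(1:2000),
                    gender_raw = "nonbinary",
                    age_group = "25-34", education = "medium",
                    urbanisation = "city", stringsAsFactors = FALSE)
  r1 <- recode_covariates(tab, seed = 42)
  r2 <- recode_covariates(tab, seed = 42)
  expect_identical(r1$gender, r2$gender)
  share <- mean(r1$gender == "male")
  expect_lt(abs(share - 0.5), 3 * sqrt(0.25 / 2000))
  # without non-binary rows, gender mirrors gender_raw
  tab2 <- within(tab, gender_raw <- rep(c("male", "female"), 1000))
  r3 <- recode_covariates(tab2, seed = 1)
  expect_identical(as.character(r3$gender), tab2$gender_raw)
  # unknown levels are reported with row and field
  tab3 <- within(tab, gender_raw <- replace(gender_raw, 7, "other"))
  expect_error(recode_covariates(tab3, seed = 1), "gender_raw.*row 7",
               class = "cannadid_recode_error")
})
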