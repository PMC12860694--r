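test_that("degenerate prevalences yield a cannabis-free table", {
  cfg <- small_config(p_use = c(control_t0 = 0, control_t1 = 0,
                                intervention_t0 = 0))
  tab <- generate_survey(cfg)
  expect_false(any(tab$cannabis_12m))
  expect_true(all(tab$cannabis_freq == "never"))
  expect_true(all(is.na(tab$duic_12m)))
})

test_that("generation is a pure function of the config and seed", {
  cfg <- small_config(artifact_rates = c(speeder = 0.01, straightliner = 0.01,
                                         control_fail = 0.01,
                                         duplicate = 0.01))
  a <- inject_artifacts(generate_survey(cfg), cfg)
  b <- inject_artifacts(generate_survey(cfg), cfg)
  expect_identical(a, b)
  cfg2 <- small_config(seed = 999)
  expect_false(identical(generate_survey(cfg2), generate_survey(cfg)))
})

test_that("cell prevalences match targets within 3 binomial SEs at study scale", {
  cfg <- generator_config(seed = 31)   # defaults: the printed cell sizes
  tab <- generate_survey(cfg)
  expect_identical(unname(table(tab$country, tab$wave)["control", "t0"]), 2132L)
  targets <- c(control_t0 = 0.094, control_t1 = 0.096,
               intervention_t0 = 0.121,
               intervention_t1 = unname(intervention_t1_prevalence(cfg)))
  for (cell in names(targets)) {
    ctry <- sub("_t[01]$", "", cell); wv <- sub("^.*_", "", cell)
    rows <- tab$country == ctry & tab$wave == wv
    phat <- mean(tab$cannabis_12m[rows])
    se <- sqrt(targets[[cell]] * (1 - targets[[cell]]) / sum(rows))
    expect_lt(abs(phat - targets[[cell]]), 3 * se)
  }
})

test_that("covariate margins are honoured within 3 multinomial SEs", {
  cfg <- small_config(seed = 77)
  tab <- generate_survey(cfg)
  n <- nrow(tab)
  for (dim in c("age_group", "education", "region")) {
    target <- cfg$margins[[dim]]
    obs <- prop.table(table(tab[[dim]]))[names(target)]
    se <- sqrt(target * (1 - target) / n)
    expect_true(all(abs(obs - target) < 3 * se), label = dim)
  }
})

test_that("instrument filter and skip logic hold row by row", {
  cfg <- small_config(p_use = c(control_t0 = 0.3, control_t1 = 0.3,
                                intervention_t0 = 0.3), seed = 13)
  tab <- generate_survey(cfg)
  # DUIC asked only at/above the per-wave threshold
  thr <- c(t0 = "monthly", t1 = "less_than_monthly")
  lev <- respondent_levels("cannabis_freq")
  asked <- !is.na(tab$duic_12m)
  should <- tab$cannabis_12m &
    match(as.character(tab$cannabis_freq), lev) >=
      match(thr[as.character(tab$wave)], lev)
  expect_identical(asked, unname(should))
  # past-30-day DUIC implies past-year DUIC
  expect_true(all(tab$duic_12m[!is.na(tab$duic_30d) & tab$duic_30d]))
  # co-use category present iff past-year DUIC reported
  expect_identical(!is.na(tab$couse_category),
                   !is.na(tab$duic_12m) & tab$duic_12m)
  # exact count present iff the open category was selected
  more <- !is.na(tab$duic_count_category) & tab$duic_count_category == "more"
  expect_identical(!is.na(tab$duic_count_exact), more)
  expect_true(all(tab$duic_count_exact[more] > 15))
  # episode granularity exists only at wave t1
  expect_true(all(is.na(tab$duic_count_category[tab$wave == "t0"])))
})

test_that("invalid configurations are rejected with the field name", {
  expect_error(small_config(freq_dist = c(less_than_monthly = 0.5,
                                          monthly = 0.5, weekly = 0.5,
                                          daily = 0.5)),
               "freq_dist", class = "cannadid_config_error")
  expect_error(generator_config(n = c(control_t0 = -5, control_t1 = 10,
                                      intervention_t0 = 10,
                                      intervention_t1 = 10)),
               "'n'", class = "cannadid_config_error")
  expect_error(small_config(or_did = -2), "or_did",
               class = "cannadid_config_error")
})

test_that("artifact injection plants exact counts and records the truth", {
  cfg <- small_config()
  tab <- generate_survey(cfg)
  same <- inject_artifacts(tab, cfg)       # all rates zero
  expect_identical(tab, structure(same, planted = NULL))
  expect_identical(nrow(planted_ledger(same)), 0L)

  r <- c(speeder = 0.02, straightliner = 0.01, control_fail = 0.01,
         duplicate = 0.012)
  cfg2 <- small_config(artifact_rates = r)
  tab2 <- inject_artifacts(generate_survey(cfg2), cfg2)
  led <- planted_ledger(tab2)
  n <- nrow(tab2)
  for (a in names(r))
    expect_identical(sum(led$artifact == a),
                     as.integer(floor(r[[a]] * n)), label = a)
  # planted duplicate ids really appear in both waves
  dup <- led$id[led$artifact == "duplicate"]
  expect_true(all(dup %in% tab2$id[tab2$wave == "t0"]))
  expect_true(all(dup %in% tab2$id[tab2$wave == "t1"]))
})

test_that("injected DiD effect is recovered by the saturated model", {
  # parameter recovery on the full microdata path at reduced size
  or_true <- 1.6
  set.seed(404)
  ests <- replicate(60, {
    cfg <- generator_config(
      n = c(control_t0 = 1500, control_t1 = 1500,
            intervention_t0 = 3000, intervention_t1 = 3000),
      or_did = or_true, seed = sample.int(1e6, 1))
    tab <- generate_survey(cfg)
    log(did_effect(tab, "cannabis_12m")$or)
  })
  mc_se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - log(or_true)), 2 * mc_se)
})
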