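# Shared fixture builders: everything is generated in code at test time.

small_config <- function(..., seed = 101) {
  generator_config(
    n = c(control_t0 = 700, control_t1 = 700,
          intervention_t0 = 1400, intervention_t1 = 1400),
    seed = seed, ...)
}

# Degenerate one-dimensional margins: only age_group varies, all other
# post-stratification dimensions are collapsed to a single level.
margins_1d <- function(props, country = "intervention") {
  population_margins(data.frame(
    country = country,
    age_group = names(props),
    gender = "male", education = "low", region = "north",
    proportion = unname(props)))
}

# A tiny respondent frame carrying only the columns a given test needs.
mini_sample <- function(age, country = "intervention", wave = "t0") {
  data.frame(country = country, wave = wave,
             age_group = age, gender = "male", education = "low",
             region = "north", stringsAsFactors = FALSE)
}

# Closed-form saturated 2x2x2 oracle: log odds / log odds ratios from counts.
count_oracle <- function(successes, trials) {
  odds <- function(i) successes[i] / (trials[i] - successes[i])
  c(intercept = log(odds(1)),
    wave = log(odds(2) / odds(1)),
    country = log(odds(3) / odds(1)),
    interaction = log((odds(4) / odds(3)) / (odds(2) / odds(1))))
}

# Random non-degenerate 2x2x2 count tables for property tests.
random_arm_table <- function() {
  n <- sample(60:400, 4, replace = TRUE)
  p <- runif(4, 0.1, 0.9)
  y <- pmin(pmax(rbinom(4, n, p), 2), n - 2)   # keep all 8 cells occupied
  list(successes = y, trials = n)
}

# Small hand-checkable episode sample for the burden module.
burden_fixture <- function() {
  s3 <- data.frame(
    id = sprintf("r%02d", 1:6),
    cannabis_freq = c("daily", "daily", "weekly", "weekly", "monthly",
                      "less_than_monthly"),
    duic_count_category = c("10-15", "4-9", "2-3", "more", "once", "once"),
    duic_count_exact = c(NA, NA, NA, 20, NA, NA),
    couse_category = c("cannabis_only", "occasionally", "mostly", "always",
                       "cannabis_only", "occasionally"),
    stringsAsFactors = FALSE)
  users <- data.frame(cannabis_freq = rep(c("less_than_monthly", "monthly",
                                            "weekly", "daily"),
                                          c(40, 25, 20, 15)))
  list(sample3 = s3, users = users)
}

# Random burden fixture for conservation / normalisation properties.
random_burden_fixture <- function() {
  n <- sample(10:40, 1)
  cats <- c("once", "2-3", "4-9", "10-15", "more")
  cat_draw <- sample(cats, n, replace = TRUE)
  s3 <- data.frame(
    cannabis_freq = sample(c("less_than_monthly", "monthly", "weekly",
                             "daily"), n, replace = TRUE),
    duic_count_category = cat_draw,
    duic_count_exact = ifelse(cat_draw == "more", sample(16:60, n, TRUE),
                              NA),
    couse_category = sample(c("cannabis_only", "occasionally", "mostly",
                              "always"), n, replace = TRUE))
  users <- data.frame(cannabis_freq = sample(
    c("less_than_monthly", "monthly", "weekly", "daily"),
    n * 5, replace = TRUE))
  list(sample3 = s3, users = users)
}

sample1_power_design <- function(nsim = 500, seed = 20) {
  power_design(n_control = c(2132, 2102), n_intervention = c(6670, 9692),
               p_control_t0 = 0.094, p_control_t1 = 0.096,
               p_intervention_t0 = 0.121, nsim = nsim, seed = seed)
}
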