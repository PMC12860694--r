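#' Apply response-quality exclusion filters
#'
#' Removes respondents with cross-wave duplicate ids, unrealistically short
#' response times, zero response variability, or failed control checks. Every
#' removed row is attributed to exactly one filter, in the fixed order
#' duplicate -> speeder -> straightliner -> control-check, so attribution is
#' deterministic when a row violates several rules. Respondents whose id
#' appears in both waves are removed from both waves.
#'
#' @param table respondent table.
#' @param thresholds list with `speeder_seconds` (exclusive lower bound on
#'   response time), `min_variability` (rows with variability at or below are
#'   excluded; default 0) and `exclude_control_fail` (logical).
#' @return list with `data` (clean table) and `log` (data.frame of filter,
#'   rows before, rows removed, in application order).
#' @export
apply_quality_filters <- function(table,
                                  thresholds = list(speeder_seconds = 180,
                                                    min_variability = 0,
                                                    exclude_control_fail = TRUE)) {
  log <- data.frame(filter = character(0), before = integer(0),
                    removed = integer(0))
  flag_order <- c("duplicate", "speeder", "straightliner", "control_check")
  if (nrow(table) == 0)
    return(list(data = table,
                log = data.frame(filter = flag_order, before = 0L,
                                 removed = 0L)))

  dup_ids <- intersect(table$id[table$wave == "t0"],
                       table$id[table$wave == "t1"])
  flags <- list(
    duplicate = table$id %in% dup_ids,
    speeder = table$response_seconds <
      (thresholds$speeder_seconds %||% 180),
    straightliner = table$variability_index <=
      (thresholds$min_variability %||% 0),
    control_check = if (isTRUE(thresholds$exclude_control_fail %||% TRUE))
      !table$control_check_pass else rep(FALSE, nrow(table))
  )
  assigned <- rep(NA_character_, nrow(table))
  for (f in flag_order) {
    hit <- flags[[f]] & is.na(assigned)
    assigned[hit] <- f
  }
  keep <- is.na(assigned)
  for (f in flag_order) {
    before <- sum(is.na(assigned) | match(assigned, flag_order) >=
                    match(f, flag_order))
    log <- rbind(log, data.frame(filter = f, before = before,
                                 removed = sum(assigned == f, na.rm = TRUE)))
  }
  clean <- table[keep, , drop = FALSE]
  rownames(clean) <- NULL
  attr(clean, "planted") <- NULL
  list(data = clean, log = log,
       removed = data.frame(id = table$id[!keep], filter = assigned[!keep]))
}

#' Survey response metrics
#'
#' Access rate (accessed / invited) and completion rate (completed /
#' accessed), as percentages rounded to one decimal.
#'
#' @param invited,accessed,completed cumulative funnel counts with
#'   `invited >= accessed >= completed >= 0`.
#' @return data.frame with columns `metric`, `numerator`, `denominator`,
#'   `rate_pct`.
#' @export
response_metrics <- function(invited, accessed, completed) {
  if (invited < accessed || accessed < completed || completed < 0)
    abort2("counts must satisfy invited >= accessed >= completed >= 0",
           "config")
  if (invited == 0 || accessed == 0)
    abort2("undefined rate: zero denominator", "degenerate_rate")
  data.frame(
    metric = c("access_rate", "completion_rate"),
    numerator = c(accessed, completed),
    denominator = c(invited, accessed),
    rate_pct = round(100 * c(accessed / invited, completed / accessed), 1)
  )
}

new_analytic_sample <- function(sample_id, data, log) {
  structure(list(sample_id = sample_id, data = data, derivation_log = log),
            class = "analytic_sample")
}

#' @export
print.analytic_sample <- function(x, ...) {
  cat(sprintf("Analytic sample %d: %d respondents\n", x$sample_id,
              nrow(x$data)))
  print(x$derivation_log, row.names = FALSE)
  invisible(x)
}

#' Derive the three analytic samples
#'
#' Sample 1: all quality-filtered respondents (general population), used for
#' the cannabis-use DiD. Sample 2: at least monthly cannabis users without
#' medical-only prescription use, both waves (the DUIC DiD sample; the
#' at-least-monthly criterion is applied at both waves for comparability).
#' Sample 3: past-year users without medical-only prescription use who report
#' DUIC in the past 30 days with complete episode-count and co-use data (the
#' episode-burden sample; episode granularity exists at wave t1 only, so this
#' sample is effectively post-legalisation).
#'
#' @param clean quality-filtered respondent table.
#' @return named list of three `analytic_sample` objects, each carrying a
#'   derivation log of (filter, rows before, rows removed).
#' @export
derive_samples <- function(clean) {
  step <- function(log, name, before, keep) {
    rbind(log, data.frame(filter = name, before = before,
                          removed = before - sum(keep)))
  }
  s1 <- new_analytic_sample(1L, clean,
                            data.frame(filter = "all_respondents",
                                       before = nrow(clean), removed = 0L))

  log2 <- data.frame(filter = character(0), before = integer(0),
                     removed = integer(0))
  k <- !is.na(clean$cannabis_freq) &
    clean$cannabis_freq %in% c("monthly", "weekly", "daily")
  log2 <- step(log2, "at_least_monthly_use", nrow(clean), k)
  d2 <- clean[k, , drop = FALSE]
  k2 <- !d2$medical_only_rx
  log2 <- step(log2, "medical_only_rx", nrow(d2), k2)
  d2 <- d2[k2, , drop = FALSE]
  rownames(d2) <- NULL
  s2 <- new_analytic_sample(2L, d2, log2)

  log3 <- data.frame(filter = character(0), before = integer(0),
                     removed = integer(0))
  k <- clean$cannabis_12m
  log3 <- step(log3, "past_year_use", nrow(clean), k)
  d3 <- clean[k, , drop = FALSE]
  k2 <- !d3$medical_only_rx
  log3 <- step(log3, "medical_only_rx", nrow(d3), k2)
  d3 <- d3[k2, , drop = FALSE]
  k3 <- !is.na(d3$duic_30d) & d3$duic_30d
  log3 <- step(log3, "duic_past_30d", nrow(d3), k3)
  d3 <- d3[k3, , drop = FALSE]
  k4 <- !is.na(d3$duic_count_category) & !is.na(d3$couse_category) &
    (d3$duic_count_category != "more" | !is.na(d3$duic_count_exact))
  log3 <- step(log3, "complete_episode_data", nrow(d3), k4)
  d3 <- d3[k4, , drop = FALSE]
  rownames(d3) <- NULL
  s3 <- new_analytic_sample(3L, d3, log3)

  list(sample1 = s1, sample2 = s2, sample3 = s3)
}

#' Recode covariates for analysis
#'
#' Assigns non-binary respondents to the male or female category by a seeded
#' fair coin (probability configurable), yielding the binary `gender` analysis
#' covariate; validates that categorical covariates carry only known levels.
#'
#' @param table respondent table with `gender_raw`.
#' @param seed integer seed for the reassignment.
#' @param p_male probability of assignment to male (default 0.5).
#' @return the table with an added `gender` factor (male/female).
#' @export
recode_covariates <- function(table, seed, p_male = 0.5) {
  for (f in c("age_group", "education", "urbanisation")) {
    bad <- !is.na(table[[f]]) & !(as.character(table[[f]]) %in% .levels[[f]])
    if (any(bad))
      abort2(sprintf("unknown level in field '%s' at row %d", f,
                     which(bad)[1]), "recode")
  }
  g <- as.character(table$gender_raw)
  bad <- !is.na(g) & !(g %in% .levels$gender_raw)
  if (any(bad))
    abort2(sprintf("unknown level in field 'gender_raw' at row %d",
                   which(bad)[1]), "recode")
  nb <- which(!is.na(g) & g == "nonbinary")
  if (length(nb)) {
    set.seed(stage_seed(seed, "recode_gender"))
    g[nb] <- ifelse(runif(length(nb)) < p_male, "male", "female")
  }
  table$gender <- factor(g, levels = .levels$gender)
  table
}
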