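freq_at_least <- function(freq, threshold) {
  lev <- .levels$cannabis_freq
  as.integer(factor(freq, lev)) >= match(threshold, lev)
}

draw_cat <- function(n, probs) {
  names(probs)[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

#' Generate a synthetic survey respondent table
#'
#' Draws a seeded respondent table for a two-country (intervention/control) by
#' two-wave (t0/t1) repeated cross-sectional design. Sociodemographic
#' covariates are drawn independently from their configured margins (the
#' design is quota-sampled on marginal distributions only). Past-year cannabis
#' use follows the configured cell prevalences, with the intervention wave-1
#' prevalence derived on the logit scale so that the saturated time-by-country
#' interaction equals the injected DiD odds ratio. DUIC items are only asked
#' of respondents at or above the per-wave frequency threshold, mirroring the
#' instrument's filter change between waves; episode-count categories are
#' collected at wave t1 only.
#'
#' @param config a [generator_config()].
#' @return a data.frame with one row per respondent (see package vignette for
#'   the column dictionary). Generation is a pure function of the config,
#'   including its seed.
#' @export
generate_survey <- function(config) {
  if (!inherits(config, "generator_config"))
    config <- do.call(generator_config, config)
  set.seed(stage_seed(config$seed, "generate"))

  p_i1 <- intervention_t1_prevalence(config)
  cell_p <- c(control_t0 = config$p_use[["control_t0"]],
              control_t1 = config$p_use[["control_t1"]],
              intervention_t0 = config$p_use[["intervention_t0"]],
              intervention_t1 = p_i1)

  blocks <- lapply(names(config$n), function(cell) {
    n <- config$n[[cell]]
    country <- sub("_t[01]$", "", cell)
    wave <- sub("^.*_", "", cell)
    mg <- config$margins
    d <- data.frame(
      id = sprintf("%s_%s_%06d", substr(country, 1, 3), wave, seq_len(n)),
      country = country, wave = wave,
      age_group = draw_cat(n, mg$age_group),
      gender_raw = draw_cat(n, mg$gender_raw),
      education = draw_cat(n, mg$education),
      region = draw_cat(n, mg$region),
      urbanisation = draw_cat(n, mg$urbanisation[[country]]),
      driver_licence = runif(n) < mg$driver_licence,
      stringsAsFactors = FALSE
    )
    d$cannabis_12m <- runif(n) < cell_p[[cell]]

    d$cannabis_freq <- "never"
    nu <- sum(d$cannabis_12m)
    if (nu > 0)
      d$cannabis_freq[d$cannabis_12m] <- draw_cat(nu, config$freq_dist)

    d$medical_only_rx <- FALSE
    d$medical_only_rx[d$cannabis_12m] <- runif(nu) < config$p_medical_rx

    d$nq_minus <- rnorm(n, config$nq_mean, config$nq_sd)

    # DUIC asked only at/above the per-wave frequency threshold
    asked <- d$cannabis_12m &
      freq_at_least(d$cannabis_freq, config$ask_threshold[[wave]])
    d$duic_12m <- NA
    if (any(asked)) {
      nq_std <- (d$nq_minus[asked] - config$nq_mean) / config$nq_sd
      eff <- config$duic_effects
      lp <- qlogis(config$p_duic12[d$cannabis_freq[asked]]) +
        log(eff[["licence_or"]]) *
          (d$driver_licence[asked] - mean(d$driver_licence)) +
        log(eff[["female_or"]]) *
          ((d$gender_raw[asked] == "female") -
             mean(d$gender_raw == "female")) +
        log(eff[["nq_or"]]) * nq_std
      d$duic_12m[asked] <- runif(sum(asked)) < plogis(lp)
    }
    d$duic_30d <- NA
    rep12 <- !is.na(d$duic_12m)
    d$duic_30d[rep12] <- d$duic_12m[rep12] &
      (runif(sum(rep12)) < config$p_duic30_given12)

    # co-use category present iff DUIC reported in the past year
    d$couse_category <- NA_character_
    cu <- rep12 & d$duic_12m
    if (any(cu)) d$couse_category[cu] <- draw_cat(sum(cu), config$couse_dist)

    # episode counts: wave-t1 instrument only
    d$duic_count_category <- NA_character_
    d$duic_count_exact <- NA_real_
    ep <- cu & !is.na(d$duic_30d) & d$duic_30d & wave == "t1"
    if (any(ep)) {
      d$duic_count_category[ep] <- draw_cat(sum(ep), config$episode_dist)
      more <- !is.na(d$duic_count_category) & d$duic_count_category == "more"
      if (any(more)) {
        excess <- rgeom(sum(more), 1 / config$episode_tail_mean) + 1
        d$duic_count_exact[more] <-
          pmin(15 + excess, config$episode_tail_max)
      }
    }

    # behavioural covariates: independent 5-level ordinals
    beh <- c(never = 0.30, less_than_monthly = 0.25, monthly = 0.15,
             weekly = 0.20, daily = 0.10)
    d$alcohol_freq <- draw_cat(n, c(never = 0.18, less_than_monthly = 0.27,
                                    monthly = 0.15, weekly = 0.30,
                                    daily = 0.10))
    d$gambling_freq <- draw_cat(n, c(never = 0.62, less_than_monthly = 0.20,
                                     monthly = 0.09, weekly = 0.07,
                                     daily = 0.02))
    d$activity_freq <- draw_cat(n, c(never = 0.08, less_than_monthly = 0.14,
                                     monthly = 0.13, weekly = 0.45,
                                     daily = 0.20))

    # response-quality metadata for clean rows: guaranteed to pass filters
    d$response_seconds <- config$speeder_seconds +
      rlnorm(n, log(400), 0.6)
    d$variability_index <- runif(n, 0.1, 1)
    d$control_check_pass <- TRUE
    d
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  for (f in c("country", "wave", "age_group", "gender_raw", "education",
              "region", "urbanisation", "cannabis_freq", "couse_category",
              "duic_count_category"))
    out[[f]] <- factor(out[[f]], levels = .levels[[f]])
  for (f in c("alcohol_freq", "gambling_freq", "activity_freq"))
    out[[f]] <- factor(out[[f]], levels = .levels$freq5)
  out
}

#' Plant response-quality artifacts in a generated table
#'
#' Plants exact counts (`floor(rate * nrow)`) of speeders (response time below
#' the configured threshold), straightliners (zero response variability),
#' control-check failures, and cross-wave duplicate ids (a t1 row reusing the
#' id of a t0 row from the same country). Artifact rows are chosen disjointly
#' so each planted row is attributable to exactly one failure. The planted
#' truth is recorded in a ledger attached as attribute `"planted"` (see
#' [planted_ledger()]), which downstream filter tests reconcile against.
#'
#' @param table respondent table from [generate_survey()].
#' @param config the same [generator_config()]; `artifact_rates` drives counts.
#' @return the table with artifact rows modified and a planted-truth ledger
#'   attached.
#' @export
inject_artifacts <- function(table, config) {
  rates <- config$artifact_rates
  if (any(rates > 1)) abort2("artifact rates must be at most 1", "config")
  set.seed(stage_seed(config$seed, "artifacts"))
  n <- nrow(table)
  ledger <- data.frame(id = character(0), artifact = character(0),
                       stringsAsFactors = FALSE)
  taken <- logical(n)

  k_dup <- floor((rates[["duplicate"]] %||% 0) * n)
  if (k_dup > 0) {
    t1_pool <- which(table$wave == "t1" & !taken)
    rows_t1 <- sample(t1_pool, k_dup)
    for (r in rows_t1) {
      src_pool <- which(table$wave == "t0" &
                          table$country == table$country[r] & !taken)
      src <- sample(src_pool, 1)
      table$id[r] <- table$id[src]
      taken[c(r, src)] <- TRUE
      ledger <- rbind(ledger, data.frame(id = table$id[src],
                                         artifact = "duplicate"))
    }
  }
  plant <- function(artifact, k, mutate) {
    if (k <= 0) return()
    rows <- sample(which(!taken), k)
    taken[rows] <<- TRUE
    table <<- mutate(table, rows)
    ledger <<- rbind(ledger, data.frame(id = table$id[rows],
                                        artifact = artifact))
  }
  plant("speeder", floor((rates[["speeder"]] %||% 0) * n),
        function(tb, i) { tb$response_seconds[i] <-
          runif(length(i), 5, config$speeder_seconds - 1); tb })
  plant("straightliner", floor((rates[["straightliner"]] %||% 0) * n),
        function(tb, i) { tb$variability_index[i] <- 0; tb })
  plant("control_fail", floor((rates[["control_fail"]] %||% 0) * n),
        function(tb, i) { tb$control_check_pass[i] <- FALSE; tb })

  attr(table, "planted") <- ledger
  table
}

#' Planted-truth ledger of an artifact-injected table
#'
#' @param table output of [inject_artifacts()].
#' @return data.frame with columns `id`, `artifact`.
#' @export
planted_ledger <- function(table) {
  attr(table, "planted") %||%
    data.frame(id = character(0), artifact = character(0))
}

#' Write / read a respondent table as CSV
#'
#' Plain-text round trip preserving the column dictionary; factor levels are
#' restored on read. The planted ledger, if present, is written alongside as
#' `<path>.ledger.csv`.
#'
#' @param table respondent table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  pl <- attr(table, "planted")
  if (!is.null(pl) && nrow(pl))
    utils::write.csv(pl, paste0(path, ".ledger.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_survey
#' @export
read_survey <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  for (f in intersect(names(.levels), names(d)))
    d[[f]] <- factor(d[[f]], levels = .levels[[f]])
  for (f in intersect(c("alcohol_freq", "gambling_freq", "activity_freq"),
                      names(d)))
    d[[f]] <- factor(d[[f]], levels = .levels$freq5)
  for (f in intersect(c("driver_licence", "cannabis_12m", "medical_only_rx",
                        "duic_12m", "duic_30d", "control_check_pass"),
                      names(d)))
    d[[f]] <- as.logical(d[[f]])
  lpath <- paste0(path, ".ledger.csv")
  if (file.exists(lpath))
    attr(d, "planted") <- utils::read.csv(lpath, stringsAsFactors = FALSE)
  d
}
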