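# Canonical factor levels shared by the generator, preprocessing and models.
.levels <- list(
  country      = c("control", "intervention"),
  wave         = c("t0", "t1"),
  age_group    = c("18-24", "25-34", "35-44", "45-64"),
  gender_raw   = c("male", "female", "nonbinary"),
  gender       = c("male", "female"),
  education    = c("low", "medium", "high"),
  region       = c("north", "east", "south", "west"),
  urbanisation = c("city", "town_suburb", "rural"),
  cannabis_freq = c("never", "less_than_monthly", "monthly", "weekly", "daily"),
  couse_category = c("cannabis_only", "occasionally", "mostly", "always"),
  duic_count_category = c("once", "2-3", "4-9", "10-15", "more"),
  freq5 = c("never", "less_than_monthly", "monthly", "weekly", "daily")
)

#' Canonical factor levels used across the pipeline
#'
#' @param field name of a respondent field.
#' @return character vector of levels.
#' @export
respondent_levels <- function(field) {
  if (!field %in% names(.levels))
    abort2(sprintf("unknown field '%s'", field), "config")
  .levels[[field]]
}

#' Default covariate margins
#'
#' Marginal quota distributions for the sociodemographic covariates, per
#' country. Age, gender and education margins are shared; the urbanisation mix
#' differs (the control country is markedly more rural). Regions are four
#' collapsed federal-state groups.
#'
#' @return named list of named probability vectors, one element per covariate,
#'   with `urbanisation` a list with one vector per country.
#' @export
default_covariate_margins <- function() {
  list(
    age_group  = c("18-24" = 0.11, "25-34" = 0.21, "35-44" = 0.22,
                   "45-64" = 0.46),
    gender_raw = c(male = 0.494, female = 0.502, nonbinary = 0.004),
    education  = c(low = 0.05, medium = 0.60, high = 0.35),
    region     = c(north = 0.25, east = 0.25, south = 0.25, west = 0.25),
    urbanisation = list(
      intervention = c(city = 0.43, town_suburb = 0.40, rural = 0.17),
      control      = c(city = 0.31, town_suburb = 0.33, rural = 0.36)
    ),
    driver_licence = 0.80
  )
}

#' Build a synthetic-survey generator configuration
#'
#' Defaults encode the study conditions of the two-country, two-wave design:
#' cell sizes 2132/2102 (control) and 6670/9692 (intervention), past-year use
#' prevalences 9.4%/9.6% (control) and 12.1% at baseline in the intervention
#' country, and an injected difference-in-differences odds ratio acting on the
#' intervention country at wave t1. The intervention wave-1 prevalence is
#' parameterised on the logit scale as
#' `logit(p_I0) + [logit(p_C1) - logit(p_C0)] + log(or_did)`, so the
#' saturated-model interaction identifies exactly the injected effect.
#'
#' @param n named sizes per cell: `control_t0`, `control_t1`,
#'   `intervention_t0`, `intervention_t1`.
#' @param p_use named use prevalences for `control_t0`, `control_t1`,
#'   `intervention_t0` (the intervention t1 prevalence is derived).
#' @param or_did injected DiD odds ratio (> 0) on past-year use.
#' @param freq_dist conditional use-frequency distribution among past-year
#'   users over less-than-monthly/monthly/weekly/daily (sums to 1).
#' @param p_duic12 baseline probability of past-year DUIC per use-frequency
#'   level (at covariate means; see `duic_effects`).
#' @param duic_effects odds ratios modulating DUIC: driver's licence,
#'   female gender, and per-SD of the social-desirability score NQ-.
#' @param p_duic30_given12 probability of past-30-day DUIC given past-year
#'   DUIC.
#' @param couse_dist distribution of the co-use category among DUIC reporters.
#' @param episode_dist distribution over 30-day episode-count categories.
#' @param episode_tail_mean mean excess above 15 for the truncated-geometric
#'   exact counts in the open "more than 15" category.
#' @param episode_tail_max cap for exact counts (the instrument's plausible
#'   maximum).
#' @param p_medical_rx probability a past-year user is a medical-only user
#'   with a prescription.
#' @param margins covariate margins, see [default_covariate_margins()].
#' @param artifact_rates rates of planted quality failures: `speeder`,
#'   `straightliner`, `control_fail`, `duplicate`.
#' @param speeder_seconds threshold below which a response time counts as
#'   unrealistically short.
#' @param nq_mean,nq_sd mean and SD of the NQ- (minimisation of negative
#'   qualities) score.
#' @param ask_threshold minimum use-frequency level at which DUIC items are
#'   asked, per wave (the instrument filter changed between waves).
#' @param seed integer seed; generation is a pure function of (config, seed).
#' @return a validated `generator_config` object.
#' @export
generator_config <- function(
    n = c(control_t0 = 2132, control_t1 = 2102,
          intervention_t0 = 6670, intervention_t1 = 9692),
    p_use = c(control_t0 = 0.094, control_t1 = 0.096,
              intervention_t0 = 0.121),
    or_did = 1.18,
    freq_dist = c(less_than_monthly = 0.413, monthly = 0.203,
                  weekly = 0.184, daily = 0.200),
    p_duic12 = c(less_than_monthly = 0.08, monthly = 0.18,
                 weekly = 0.24, daily = 0.30),
    duic_effects = c(licence_or = 2.0, female_or = 0.7, nq_or = 0.6),
    p_duic30_given12 = 0.45,
    couse_dist = c(cannabis_only = 0.55, occasionally = 0.25,
                   mostly = 0.12, always = 0.08),
    episode_dist = c("once" = 0.30, "2-3" = 0.35, "4-9" = 0.22,
                     "10-15" = 0.08, "more" = 0.05),
    episode_tail_mean = 10,
    episode_tail_max = 60,
    p_medical_rx = 0.03,
    margins = default_covariate_margins(),
    artifact_rates = c(speeder = 0, straightliner = 0,
                       control_fail = 0, duplicate = 0),
    speeder_seconds = 180,
    nq_mean = 0, nq_sd = 1,
    ask_threshold = c(t0 = "monthly", t1 = "less_than_monthly"),
    seed = 1L) {

  check_count(n, "n")
  if (!all(c("control_t0", "control_t1", "intervention_t0",
             "intervention_t1") %in% names(n)))
    abort2("field 'n' must name all four (country, wave) cells", "config")
  check_prob(p_use, "p_use")
  if (!all(c("control_t0", "control_t1", "intervention_t0") %in% names(p_use)))
    abort2("field 'p_use' must name control_t0, control_t1, intervention_t0",
           "config")
  if (!is.numeric(or_did) || length(or_did) != 1 || or_did <= 0)
    abort2("field 'or_did' must be a positive odds ratio", "config")
  check_simplex(freq_dist, "freq_dist")
  check_prob(p_duic12, "p_duic12")
  check_prob(p_duic30_given12, "p_duic30_given12")
  check_simplex(couse_dist, "couse_dist")
  check_simplex(episode_dist, "episode_dist")
  check_prob(p_medical_rx, "p_medical_rx")
  check_prob(artifact_rates, "artifact_rates")
  if (episode_tail_mean <= 0) abort2("field 'episode_tail_mean' must be > 0",
                                     "config")
  check_simplex(margins$age_group, "margins$age_group")
  check_simplex(margins$gender_raw, "margins$gender_raw")
  check_simplex(margins$education, "margins$education")
  check_simplex(margins$region, "margins$region")
  for (ctry in c("intervention", "control"))
    check_simplex(margins$urbanisation[[ctry]],
                  paste0("margins$urbanisation$", ctry))
  check_prob(margins$driver_licence, "margins$driver_licence")
  if (!all(ask_threshold %in% .levels$cannabis_freq[-1]))
    abort2("field 'ask_threshold' has unknown frequency level", "config")

  structure(
    list(n = n, p_use = p_use, or_did = or_did, freq_dist = freq_dist,
         p_duic12 = p_duic12, duic_effects = duic_effects,
         p_duic30_given12 = p_duic30_given12, couse_dist = couse_dist,
         episode_dist = episode_dist, episode_tail_mean = episode_tail_mean,
         episode_tail_max = episode_tail_max, p_medical_rx = p_medical_rx,
         margins = margins, artifact_rates = artifact_rates,
         speeder_seconds = speeder_seconds, nq_mean = nq_mean, nq_sd = nq_sd,
         ask_threshold = ask_threshold, seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Derived intervention wave-1 use prevalence
#'
#' `plogis(qlogis(p_I0) + qlogis(p_C1) - qlogis(p_C0) + log(or_did))`:
#' control-trend-adjusted baseline odds times the injected DiD odds ratio.
#'
#' @param config a `generator_config`.
#' @return probability.
#' @export
intervention_t1_prevalence <- function(config) {
  p <- config$p_use
  anchors <- c(p[["intervention_t0"]], p[["control_t0"]], p[["control_t1"]])
  # degenerate anchors (0 or 1) have no logit; pass the baseline through
  if (any(anchors <= 0) || any(anchors >= 1))
    return(unname(p[["intervention_t0"]]))
  plogis(qlogis(p[["intervention_t0"]]) +
           (qlogis(p[["control_t1"]]) - qlogis(p[["control_t0"]])) +
           log(config$or_did))
}

#' Read a generator configuration from YAML or JSON
#'
#' Scalar and vector fields present in the file override the defaults of
#' [generator_config()]; named vectors are given as mappings.
#'
#' @param path file path ending in .yaml/.yml or .json.
#' @return a `generator_config`.
#' @export
read_generator_config <- function(path) {
  if (!file.exists(path)) abort2(sprintf("config file '%s' not found", path),
                                 "config")
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  raw <- lapply(raw, function(x) if (is.list(x) && !is.list(x[[1]]))
    unlist(x) else x)
  do.call(generator_config, raw)
}
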