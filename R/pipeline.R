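default_run_config <- function() {
  list(
    seed = 1L,
    output_dir = "results/run",
    stages = c("generate", "preprocess", "weight", "did", "power", "burden"),
    generator = list(),
    thresholds = list(speeder_seconds = 180, min_variability = 0,
                      exclude_control_fail = TRUE),
    weighting = list(mode = "raking"),
    models = list(
      list(name = "h1_use_weighted", sample = 1, outcome = "cannabis_12m",
           weighted = TRUE, covariates = character(0)),
      list(name = "h2_duic_adjusted", sample = 2, outcome = "duic_12m",
           weighted = FALSE,
           covariates = c("gender", "driver_licence", "age_group",
                          "education"))
    ),
    power = list(
      list(name = "sample1", n_control = c(2132, 2102),
           n_intervention = c(6670, 9692),
           p_control_t0 = 0.094, p_control_t1 = 0.096,
           p_intervention_t0 = 0.121, nsim = 500),
      list(name = "sample2", n_control = c(86, 92),
           n_intervention = c(393, 589),
           p_control_t0 = 0.128, p_control_t1 = 0.163,
           p_intervention_t0 = 0.285, nsim = 500)
    ),
    burden = list(B = 2000, schemes = list(primary = c(1, 0.75, 0.25, 0)))
  )
}

read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      abort2(sprintf("config file '%s' not found", config), "validation")
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(default_run_config(), config)
  # unnamed list-of-list keys replace wholesale rather than merging
  for (k in c("models", "power", "stages"))
    if (!is.null(config[[k]])) cfg[[k]] <- config[[k]]
  if (!is.null(config$burden$schemes))
    cfg$burden$schemes <- config$burden$schemes
  bad <- setdiff(cfg$stages, c("generate", "preprocess", "weight", "did",
                               "power", "burden"))
  if (length(bad))
    abort2(paste("unknown stage(s) in key 'stages':",
                 paste(bad, collapse = ", ")), "validation")
  if (is.null(cfg$seed) && length(cfg$stages))
    abort2("key 'seed' must be set when stochastic stages are enabled",
           "validation")
  if ("weight" %in% cfg$stages && is.null(cfg$weighting$mode))
    abort2("key 'weighting.mode' required when stage 'weight' is enabled",
           "validation")
  if ("generate" %in% cfg$stages == FALSE && is.null(cfg$input_csv) &&
      any(c("preprocess", "weight", "did", "burden") %in% cfg$stages))
    abort2("key 'input_csv' required when stage 'generate' is disabled",
           "validation")
  cfg
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in fixed order — generate, preprocess, weight,
#' did, power, burden — writing per-stage CSV/JSON outputs, derivation logs,
#' and a single `summary.json` (coefficient tables, MDE results, burden
#' tables) to the output directory. Outputs are a pure function of
#' (config, seed): the global seed is fanned out to per-stage substreams by
#' stable stage names, so toggling one stage never perturbs another. Every
#' run writes a `manifest.json` carrying the seed and a content hash of the
#' resolved configuration.
#'
#' @param config a configuration list, or the path of a YAML/JSON file; see
#'   the package vignette for the schema. Omitted keys take defaults.
#' @return invisibly, a list with the resolved config and the stage results.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- read_run_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list(config = cfg)
  hcfg <- cfg; hcfg$output_dir <- NULL   # hash the analysis parameters only
  summary <- list(seed = cfg$seed, config_hash = object_hash(hcfg))
  path <- function(f) file.path(cfg$output_dir, f)

  gcfg <- do.call(generator_config,
                  c(cfg$generator, list(seed = stage_seed(cfg$seed,
                                                          "microdata"))))
  if ("generate" %in% cfg$stages) {
    tab <- generate_survey(gcfg)
    tab <- inject_artifacts(tab, gcfg)
    write_survey(tab, path("survey.csv"))
    out$survey <- tab
  } else if (!is.null(cfg$input_csv)) {
    out$survey <- read_survey(cfg$input_csv)
  }

  if ("preprocess" %in% cfg$stages) {
    fl <- apply_quality_filters(out$survey, cfg$thresholds)
    clean <- recode_covariates(fl$data, seed = stage_seed(cfg$seed, "recode"))
    out$samples <- derive_samples(clean)
    utils::write.csv(fl$log, path("exclusion_log.csv"), row.names = FALSE)
    for (s in out$samples)
      utils::write.csv(s$derivation_log,
                       path(sprintf("sample%d_derivation.csv", s$sample_id)),
                       row.names = FALSE)
    summary$sample_sizes <- vapply(out$samples, function(s) nrow(s$data),
                                   integer(1))
  }

  if ("weight" %in% cfg$stages) {
    margins <- if (!is.null(cfg$margins_csv))
      population_margins(utils::read.csv(cfg$margins_csv)) else
        margins_from_config(gcfg)
    wd <- poststratify(out$samples$sample1$data, margins,
                       mode = cfg$weighting$mode)
    out$weighted <- wd
    utils::write.csv(wd$data[c("id", "weight")], path("weights.csv"),
                     row.names = FALSE)
    summary$weighting <- wd$diagnostics
  }

  if ("did" %in% cfg$stages) {
    out$did <- list()
    for (m in cfg$models) {
      d <- if (m$sample == 1 && isTRUE(m$weighted) && !is.null(out$weighted))
        out$weighted$data
      else out$samples[[paste0("sample", m$sample)]]$data
      w <- if (isTRUE(m$weighted)) d$weight else NULL
      res <- did_effect(d, m$outcome, covariates = m$covariates %||%
                          character(0), weights = w)
      out$did[[m$name]] <- res
      utils::write.csv(res$table, path(sprintf("did_%s.csv", m$name)),
                       row.names = FALSE)
      summary$did[[m$name]] <- list(
        or = res$or, ci_low = res$ci_low, ci_high = res$ci_high,
        p_value = res$p_value, n = res$n, nagelkerke = res$nagelkerke,
        model_chisq = res$model_chisq, model_df = res$model_df)
    }
  }

  if ("power" %in% cfg$stages) {
    out$power <- list()
    for (pw in cfg$power) {
      des <- power_design(
        n_control = pw$n_control, n_intervention = pw$n_intervention,
        p_control_t0 = pw$p_control_t0, p_control_t1 = pw$p_control_t1,
        p_intervention_t0 = pw$p_intervention_t0,
        nsim = pw$nsim %||% 2000,
        or_bracket = pw$or_bracket,
        seed = stage_seed(cfg$seed, paste0("power_", pw$name)))
      mde <- minimum_detectable_effect(des)
      out$power[[pw$name]] <- mde
      utils::write.csv(mde$curve, path(sprintf("power_curve_%s.csv",
                                               pw$name)), row.names = FALSE)
      summary$power[[pw$name]] <- list(mde_or = mde$mde_or,
                                       analytic_or = mde$analytic_or)
    }
  }

  if ("burden" %in% cfg$stages) {
    s3 <- out$samples$sample3$data
    users <- out$samples$sample1$data
    users <- users[users$cannabis_12m & !users$medical_only_rx, ,
                   drop = FALSE]
    schemes <- lapply(cfg$burden$schemes, function(v)
      do.call(allocation_scheme, as.list(v)))
    bt <- bootstrap_burden(s3, users, schemes[[1]],
                           B = cfg$burden$B %||% 2000,
                           seed = stage_seed(cfg$seed, "burden"))
    out$burden <- bt
    utils::write.csv(as.data.frame(bt), path("burden.csv"),
                     row.names = FALSE)
    if (length(schemes) > 1)
      out$burden_sensitivity <- sensitivity_schemes(s3, users, schemes[-1])
    tt <- burden_totals(bt)
    summary$burden <- list(total_episodes = tt$total,
                           minus_episodes = tt$minus,
                           plus_episodes = tt$plus,
                           plus_proportion_pct = tt$plus_proportion,
                           n_respondents = tt$n_respondents)
  }

  write_json_out(summary, path("summary.json"))
  write_json_out(list(seed = cfg$seed, config_hash = object_hash(hcfg),
                      stages = cfg$stages), path("manifest.json"))
  invisible(out)
}

#' Write a small packaged fixture dataset
#'
#' Profiles: `"null-effect"` (reduced cell sizes, injected DiD odds ratio 1),
#' `"paper-scale"` (the study's printed cell sizes and anchor prevalences),
#' `"burden-demo"` (small, high-prevalence cells so the episode sample is
#' well populated across all co-use categories). Writes the survey CSV, the
#' planted-truth ledger, and a `truth.json` with the generating parameters.
#'
#' @param profile one of the profile names above.
#' @param seed integer seed.
#' @param dir output directory.
#' @return invisibly, the generator config used.
#' @export
make_fixture <- function(profile, seed = 1L, dir = ".") {
  cfgs <- list(
    "null-effect" = list(
      n = c(control_t0 = 600, control_t1 = 600,
            intervention_t0 = 1200, intervention_t1 = 1200),
      or_did = 1,
      artifact_rates = c(speeder = 0.01, straightliner = 0.01,
                         control_fail = 0.005, duplicate = 0.005)),
    "paper-scale" = list(
      n = c(control_t0 = 2132, control_t1 = 2102,
            intervention_t0 = 6670, intervention_t1 = 9692),
      or_did = 1.18),
    "burden-demo" = list(
      n = c(control_t0 = 300, control_t1 = 300,
            intervention_t0 = 600, intervention_t1 = 600),
      p_use = c(control_t0 = 0.45, control_t1 = 0.45,
                intervention_t0 = 0.5),
      or_did = 1,
      p_duic12 = c(less_than_monthly = 0.3, monthly = 0.45, weekly = 0.55,
                   daily = 0.6),
      p_duic30_given12 = 0.7)
  )
  if (!profile %in% names(cfgs))
    abort2(paste("unknown profile; available:",
                 paste(names(cfgs), collapse = ", ")), "config")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- do.call(generator_config, c(cfgs[[profile]], list(seed = seed)))
  tab <- inject_artifacts(generate_survey(cfg), cfg)
  write_survey(tab, file.path(dir, paste0(profile, ".csv")))
  truth <- cfg
  truth$margins <- NULL
  write_json_out(unclass(truth), file.path(dir, paste0(profile,
                                                       "_truth.json")))
  invisible(cfg)
}
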