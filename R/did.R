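#' Difference-in-differences logistic model
#'
#' Fits `outcome ~ wave * country + covariates` by weighted logistic IRLS with
#' treatment (dummy) coding, references t0 / control / the first level of each
#' covariate, and reports the time-by-country interaction odds ratio with a
#' Wald 95% confidence interval and two-sided p-value — the DiD effect. A
#' significant interaction indicates a differential change in the
#' intervention country relative to the control. Also reports the full OR
#' table, Nagelkerke R-squared, the model likelihood-ratio chi-square, and
#' per-term GVIFs.
#'
#' @param data data.frame with factor columns `wave` (t0/t1) and `country`
#'   (control/intervention), the outcome, any covariates, and optionally a
#'   `weight` column.
#' @param outcome name of a binary (or proportion, with `weights` = trials)
#'   outcome column.
#' @param covariates character vector of covariate column names (factors or
#'   numeric).
#' @param weights optional numeric weights; defaults to `data$weight` if
#'   present, else unweighted. Post-stratification weights enter as
#'   frequency-style case weights, so the reported intervals are model-based.
#' @param conf confidence level (default 0.95).
#' @return a `did_result`: `or`, `ci_low`, `ci_high`, `p_value` for the
#'   interaction, `table` of all terms, `nagelkerke`, `model_chisq`,
#'   `model_df`, `gvif`, and the underlying `fit`.
#' @export
did_effect <- function(data, outcome, covariates = character(),
                       weights = NULL, conf = 0.95) {
  data$wave <- factor(as.character(data$wave), levels = .levels$wave)
  data$country <- factor(as.character(data$country), levels = .levels$country)
  rhs <- paste(c("wave * country", covariates), collapse = " + ")
  fml <- stats::as.formula(paste("~", rhs))
  keep <- stats::complete.cases(data[c(outcome, "wave", "country",
                                       covariates)])
  d <- droplevels(data[keep, , drop = FALSE])
  mm <- stats::model.matrix(fml, d)
  w <- weights
  if (is.null(w) && "weight" %in% names(data)) w <- data$weight
  if (!is.null(w)) w <- w[keep]

  fit <- fit_logistic_irls(mm, d[[outcome]], w)
  attr(fit, "term_assign") <- attr(mm, "assign")[-1]
  attr(fit, "term_labels") <-
    attr(stats::terms(fml), "term.labels")[attr(mm, "assign")[-1]]

  z <- stats::qnorm(1 - (1 - conf) / 2)
  b <- fit$coefficients
  se <- sqrt(diag(fit$vcov))
  tab <- data.frame(
    term = names(b), estimate = b, se = se, or = exp(b),
    ci_low = exp(b - z * se), ci_high = exp(b + z * se),
    p_value = 2 * stats::pnorm(-abs(b / se)), row.names = NULL)

  int <- grep(":", names(b), value = TRUE)
  if (!length(int))
    abort2("model has no time-by-country interaction term", "config")
  i <- match(int[1], tab$term)

  gv <- if (length(unique(attr(fit, "term_assign"))) >= 2)
    gvif(fit) else NULL

  structure(list(
    or = tab$or[i], ci_low = tab$ci_low[i], ci_high = tab$ci_high[i],
    p_value = tab$p_value[i], interaction_term = int[1], table = tab,
    nagelkerke = nagelkerke_r2(fit),
    model_chisq = 2 * (fit$loglik - fit$null_loglik),
    model_df = length(b) - 1, gvif = gv, n = fit$n, fit = fit),
    class = "did_result")
}

#' @export
print.did_result <- function(x, digits = 3, ...) {
  cat(sprintf("DiD effect (%s): OR = %.2f (%.2f-%.2f), p = %.3f\n",
              x$interaction_term, x$or, x$ci_low, x$ci_high, x$p_value))
  cat(sprintf("n = %d; Nagelkerke R2 = %.3f; model chi2(%d) = %.1f\n",
              x$n, x$nagelkerke, x$model_df, x$model_chisq))
  tb <- x$table
  tb[-1] <- lapply(tb[-1], round, digits)
  print(tb, row.names = FALSE)
  invisible(x)
}

#' DiD model from aggregated arm counts
#'
#' Saturated time-by-country logistic model fitted on the four aggregated
#' binomial arms (successes out of trials), equivalent to the respondent-level
#' fit. Arm order: control t0, control t1, intervention t0, intervention t1.
#'
#' @param successes,trials numeric vectors of length 4 in the order above.
#' @return a `did_result`.
#' @export
did_effect_counts <- function(successes, trials) {
  stopifnot(length(successes) == 4, length(trials) == 4)
  d <- data.frame(
    country = factor(c("control", "control", "intervention", "intervention"),
                     levels = .levels$country),
    wave = factor(c("t0", "t1", "t0", "t1"), levels = .levels$wave),
    y = successes / trials)
  did_effect(d, "y", weights = trials)
}

#' Screen candidate covariates against an outcome
#'
#' Pearson chi-square test of each candidate covariate against the outcome on
#' the baseline (t0) sample pooled across countries; candidates with p below
#' `alpha` (default 0.10) are selected for the adjusted models. Candidates
#' with fewer than two observed levels are skipped with a warning.
#'
#' @param data baseline pooled data.frame.
#' @param outcome binary outcome column name.
#' @param candidates character vector of covariate names.
#' @param alpha inclusion threshold on the p-value (default 0.10).
#' @return data.frame of covariate, statistic, df, p_value, selected.
#' @export
screen_covariates <- function(data, outcome, candidates, alpha = 0.10) {
  out <- data.frame(covariate = character(0), statistic = numeric(0),
                    df = numeric(0), p_value = numeric(0),
                    selected = logical(0))
  y <- data[[outcome]]
  for (cv in candidates) {
    ok <- !is.na(y) & !is.na(data[[cv]])
    x <- droplevels(factor(data[[cv]][ok]))
    yy <- droplevels(factor(y[ok]))
    if (nlevels(x) < 2 || nlevels(yy) < 2) {
      warning(sprintf("covariate '%s' has a single level; skipped", cv))
      next
    }
    ct <- suppressWarnings(stats::chisq.test(x, yy, correct = FALSE))
    out <- rbind(out, data.frame(
      covariate = cv, statistic = unname(ct$statistic),
      df = unname(ct$parameter), p_value = ct$p.value,
      selected = ct$p.value < alpha))
  }
  out
}

#' Impute DUIC status for the baseline less-than-monthly subgroup
#'
#' The baseline instrument did not ask DUIC of less-than-monthly users;
#' for the total-population sensitivity model their baseline DUIC status is
#' imputed from the corresponding follow-up rate. Deterministic mode assigns
#' the expected number of cases by largest-remainder rounding (in stable id
#' order); stochastic mode draws Bernoulli(rate) with a seed.
#'
#' @param data respondent table.
#' @param rate follow-up DUIC rate among less-than-monthly users, in [0, 1].
#' @param mode `"deterministic"` or `"stochastic"`.
#' @param seed seed for stochastic mode.
#' @return the table with `duic_12m` filled for the target subgroup and an
#'   `imputation` attribute recording mode and counts.
#' @export
impute_subgroup <- function(data, rate, mode = c("deterministic", "stochastic"),
                            seed = NULL) {
  mode <- match.arg(mode)
  check_prob(rate, "rate")
  idx <- which(data$wave == "t0" &
                 data$cannabis_freq == "less_than_monthly" &
                 is.na(data$duic_12m))
  if (!length(idx)) {
    warning("no rows to impute: empty baseline less-than-monthly subgroup")
    attr(data, "imputation") <- list(mode = mode, n = 0L, imputed_true = 0L)
    return(data)
  }
  if (mode == "deterministic") {
    n <- length(idx)
    k <- floor(n * rate)
    if (n * rate - k >= 0.5) k <- k + 1      # largest remainder, two classes
    ord <- idx[order(data$id[idx])]
    data$duic_12m[ord] <- c(rep(TRUE, k), rep(FALSE, n - k))
  } else {
    set.seed(stage_seed(seed %||% 0, "impute_subgroup"))
    data$duic_12m[idx] <- stats::runif(length(idx)) < rate
    k <- sum(data$duic_12m[idx])
  }
  attr(data, "imputation") <- list(mode = mode, n = length(idx),
                                   imputed_true = as.integer(k), rate = rate)
  data
}

#' Bootstrap percentile confidence interval for a (weighted) prevalence
#'
#' Resamples respondents with replacement, within strata if given (e.g.
#' country by wave), recomputing the weighted prevalence per resample.
#'
#' @param x logical or 0/1 outcome vector.
#' @param weights optional positive weights.
#' @param strata optional stratum labels; resampling is within stratum and
#'   estimates are returned per stratum.
#' @param B number of resamples (default 2000).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return data.frame with `stratum`, `estimate`, `ci_low`, `ci_high`, `n`.
#' @export
bootstrap_prevalence <- function(x, weights = NULL, strata = NULL, B = 2000,
                                 seed = NULL, conf = 0.95) {
  stopifnot(B >= 1)
  x <- as.numeric(x)
  w <- weights %||% rep(1, length(x))
  s <- strata %||% rep("all", length(x))
  set.seed(stage_seed(seed %||% 0, "bootstrap_prevalence"))
  a <- (1 - conf) / 2
  out <- lapply(unique(s), function(st) {
    idx <- which(s == st)
    if (!length(idx)) abort2(sprintf("empty stratum '%s'", st), "config")
    xi <- x[idx]; wi <- w[idx]; n <- length(idx)
    reps <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n)
    est <- colSums(matrix(xi[reps] * wi[reps], nrow = n)) /
      colSums(matrix(wi[reps], nrow = n))
    data.frame(stratum = st, estimate = sum(xi * wi) / sum(wi),
               ci_low = unname(stats::quantile(est, a)),
               ci_high = unname(stats::quantile(est, 1 - a)), n = n)
  })
  do.call(rbind, out)
}
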