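ps_dims <- c("age_group", "gender", "education", "region")

#' Build a population-margins table
#'
#' Post-stratification targets per country: the joint distribution over the
#' age-group x gender x education x region cells, as proportions summing to 1
#' within each country.
#'
#' @param df data.frame with columns `country`, the four cell dimensions and
#'   `proportion`.
#' @return validated `population_margins` object.
#' @export
population_margins <- function(df) {
  need <- c("country", ps_dims, "proportion")
  if (!all(need %in% names(df)))
    abort2(paste("margins need columns:", paste(need, collapse = ", ")),
           "config")
  if (any(df$proportion < 0))
    abort2("margin proportions must be nonnegative", "config")
  for (ctry in unique(df$country)) {
    s <- sum(df$proportion[df$country == ctry])
    if (abs(s - 1) > 1e-9)
      abort2(sprintf("margins for country '%s' sum to %.12f, not 1", ctry, s),
             "config")
  }
  structure(df, class = c("population_margins", "data.frame"))
}

#' Margins implied by a generator configuration
#'
#' The generator draws covariates independently from their margins, so the
#' implied joint cell distribution is the outer product of the marginal
#' distributions (identical for both countries apart from the binary gender
#' collapse, which pools the non-binary margin mass proportionally).
#'
#' @param config a [generator_config()].
#' @return a [population_margins()] table covering both countries.
#' @export
margins_from_config <- function(config) {
  mg <- config$margins
  gr <- mg$gender_raw
  gender <- c(male = unname(gr[["male"]] + gr[["nonbinary"]] / 2),
              female = unname(gr[["female"]] + gr[["nonbinary"]] / 2))
  cells <- expand.grid(age_group = names(mg$age_group),
                       gender = names(gender),
                       education = names(mg$education),
                       region = names(mg$region),
                       stringsAsFactors = FALSE)
  cells$proportion <- mg$age_group[cells$age_group] * gender[cells$gender] *
    mg$education[cells$education] * mg$region[cells$region]
  out <- do.call(rbind, lapply(c("control", "intervention"), function(ctry)
    cbind(country = ctry, cells)))
  population_margins(out)
}

cell_key <- function(df) do.call(paste, c(df[ps_dims], sep = "\r"))

#' Post-stratification weighting
#'
#' Computes per-respondent weights aligning the sample's covariate
#' distribution with population margins, separately within each
#' (country, wave) group, and renormalised to mean 1 per group so weighted
#' totals equal sample sizes.
#'
#' Cell mode sets weight = target share / sample share per joint cell and
#' requires every positive-target cell to be occupied. Raking iterates
#' proportional fitting over the four marginal dimensions until all weighted
#' marginals match targets within `tol` (default 1e-8) or 100 iterations.
#'
#' @param sample respondent table with `country`, `wave`, and the four
#'   post-stratification dimensions (binary `gender`; run
#'   [recode_covariates()] first).
#' @param margins a [population_margins()] table.
#' @param mode `"cell"` or `"raking"`.
#' @param tol raking convergence tolerance on marginal discrepancies.
#' @return a `weighted_design`: the sample with a `weight` column, plus
#'   diagnostics (see [weight_diagnostics()]).
#' @export
poststratify <- function(sample, margins, mode = c("cell", "raking"),
                         tol = 1e-8) {
  mode <- match.arg(mode)
  if (any(is.na(sample$gender)))
    abort2("sample has missing 'gender'; run recode_covariates() first",
           "config")
  sample$weight <- NA_real_
  for (ctry in unique(as.character(sample$country))) {
    m <- margins[margins$country == ctry, , drop = FALSE]
    if (nrow(m) == 0)
      abort2(sprintf("no margins for country '%s'", ctry), "config")
    for (wv in unique(as.character(sample$wave))) {
      idx <- which(sample$country == ctry & sample$wave == wv)
      if (!length(idx)) next
      grp <- sample[idx, , drop = FALSE]
      w <- if (mode == "cell") cell_weights(grp, m)
           else rake_weights(grp, m, tol = tol)
      sample$weight[idx] <- w / mean(w)
    }
  }
  structure(list(data = sample, mode = mode,
                 diagnostics = weight_diagnostics(sample$weight)),
            class = "weighted_design")
}

cell_weights <- function(grp, m) {
  key_s <- cell_key(grp)
  key_m <- cell_key(m)
  target <- m$proportion[match(key_s, key_m)]
  target[is.na(target)] <- 0
  share <- as.vector(table(key_s)[key_s]) / nrow(grp)
  empty <- setdiff(key_m[m$proportion > 0], key_s)
  if (length(empty))
    abort2(sprintf(paste("post-stratification cell '%s' has positive target",
                         "share but no sample rows; consider mode = 'raking'"),
                   gsub("\r", " / ", empty[1])), "degenerate_cell")
  target / share
}

rake_weights <- function(grp, m, tol = 1e-8, max_iter = 100) {
  w <- rep(1, nrow(grp))
  marg <- lapply(ps_dims, function(d) tapply(m$proportion, m[[d]], sum))
  names(marg) <- ps_dims
  for (it in seq_len(max_iter)) {
    resid <- 0
    for (d in ps_dims) {
      lv <- as.character(grp[[d]])
      cur <- tapply(w, lv, sum) / sum(w)
      tgt <- marg[[d]][names(cur)]
      adj <- tgt / cur
      w <- w * adj[lv]
      resid <- max(resid, max(abs(cur - tgt)))
    }
    # re-measure after the sweep
    resid <- max(vapply(ps_dims, function(d) {
      cur <- tapply(w, as.character(grp[[d]]), sum) / sum(w)
      max(abs(cur - marg[[d]][names(cur)]))
    }, numeric(1)))
    if (resid < tol) return(w)
  }
  abort2(sprintf("raking did not converge in %d iterations (last residual %g)",
                 max_iter, resid), "raking")
}

#' Weight diagnostics
#'
#' Minimum, maximum and mean weight, Kish effective sample size
#' ESS = (sum w)^2 / sum w^2, and the design effect n * sum(w^2) / (sum w)^2.
#'
#' @param design a `weighted_design` or a numeric weight vector.
#' @return list with `min`, `max`, `mean`, `kish_ess`, `design_effect`, `n`.
#' @export
weight_diagnostics <- function(design) {
  w <- if (inherits(design, "weighted_design")) design$data$weight else design
  if (any(is.na(w)) || any(w <= 0)) abort2("weights must be positive",
                                           "config")
  n <- length(w)
  list(min = min(w), max = max(w), mean = mean(w),
       kish_ess = sum(w)^2 / sum(w^2),
       design_effect = n * sum(w^2) / sum(w)^2, n = n)
}

#' @export
print.weighted_design <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf(
    "Weighted design (%s): n = %d, weights %.3f-%.3f, ESS = %.1f, deff = %.3f\n",
    x$mode, d$n, d$min, d$max, d$kish_ess, d$design_effect))
  invisible(x)
}

#' Rao-Scott corrected chi-square test
#'
#' Pearson chi-square on the weighted two-way table rescaled to the actual
#' sample size, divided by the Kish design effect of the weights (first-order
#' Rao-Scott correction); p-value from the chi-square distribution on
#' (r-1)(c-1) degrees of freedom.
#'
#' @param x,y categorical vectors of equal length.
#' @param w weights (default: all 1, reducing to the ordinary Pearson test).
#' @return list with `statistic` (adjusted), `raw_statistic`, `df`,
#'   `p_value`, `design_effect`.
#' @export
rao_scott_chisq <- function(x, y, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  keep <- !is.na(x) & !is.na(y)
  x <- droplevels(factor(x[keep])); y <- droplevels(factor(y[keep]))
  w <- w[keep]
  n <- length(x)
  tab <- tapply(w, list(x, y), sum, default = 0)
  tab <- tab * n / sum(tab)                    # scale weighted counts to n
  if (nrow(tab) < 2 || ncol(tab) < 2 ||
      any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    abort2("degenerate table: need >= 2 non-empty rows and columns",
           "degenerate_table")
  expd <- outer(rowSums(tab), colSums(tab)) / n
  x2 <- sum((tab - expd)^2 / expd)
  deff <- n * sum(w^2) / sum(w)^2
  stat <- x2 / deff
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, raw_statistic = x2, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       design_effect = deff)
}
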