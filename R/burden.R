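#' Allocation scheme for DUIC(-) versus DUIC(+) episodes
#'
#' Fraction of a respondent's DUIC episodes classified as cannabis-only
#' (DUIC(-)) for each co-use category; the remainder is DUIC(+), i.e.
#' involved alcohol or other drugs. The primary scheme is 100% / 75% / 25% /
#' 0% for cannabis-only / occasionally / mostly / always.
#'
#' @param cannabis_only,occasionally,mostly,always fractions in [0, 1].
#' @return named `allocation_scheme` vector.
#' @export
allocation_scheme <- function(cannabis_only = 1, occasionally = 0.75,
                              mostly = 0.25, always = 0) {
  s <- c(cannabis_only = cannabis_only, occasionally = occasionally,
         mostly = mostly, always = always)
  check_prob(s, "allocation scheme")
  structure(s, class = "allocation_scheme")
}

#' Numeric episode count from the categorical 30-day item
#'
#' Interval categories are converted to their midpoints: once -> 1,
#' 2-3 -> 2.5, 4-9 -> 6.5, 10-15 -> 12.5; the open category uses the exact
#' entered count (> 15).
#'
#' @param category vector of categories among once, 2-3, 4-9, 10-15, more.
#' @param exact_count exact counts, required (and > 15) where
#'   `category == "more"`.
#' @return numeric episode counts.
#' @export
code_count_category <- function(category, exact_count = NULL) {
  category <- as.character(category)
  mid <- c("once" = 1, "2-3" = 2.5, "4-9" = 6.5, "10-15" = 12.5)
  bad <- !is.na(category) & !(category %in% c(names(mid), "more"))
  if (any(bad))
    abort2(sprintf("unknown episode category '%s'", category[bad][1]),
           "config")
  out <- unname(mid[category])
  more <- !is.na(category) & category == "more"
  if (any(more)) {
    ec <- if (is.null(exact_count)) rep(NA_real_, length(category))
          else exact_count
    if (any(is.na(ec[more])))
      abort2("incomplete record: category 'more' without an exact count",
             "incomplete_record")
    if (any(ec[more] <= 15))
      abort2("exact count for category 'more' must exceed 15",
             "incomplete_record")
    out[more] <- ec[more]
  }
  out
}

#' Split episode counts into DUIC(-) and DUIC(+)
#'
#' `minus = count * scheme[couse_category]`, `plus = count - minus`, so the
#' split is proportional and fractional episode counts are retained.
#'
#' @param count nonnegative episode counts.
#' @param couse_category co-use categories (levels of the scheme).
#' @param scheme an [allocation_scheme()].
#' @return data.frame with columns `minus`, `plus`, `total`.
#' @export
allocate_episodes <- function(count, couse_category,
                              scheme = allocation_scheme()) {
  if (any(count < 0, na.rm = TRUE))
    abort2("episode counts must be nonnegative", "config")
  cc <- as.character(couse_category)
  bad <- !is.na(cc) & !(cc %in% names(scheme))
  if (any(bad))
    abort2(sprintf("unknown co-use category '%s'", cc[bad][1]), "config")
  minus <- count * unname(unclass(scheme)[cc])
  data.frame(minus = minus, plus = count - minus, total = count)
}

freq_groups_s3 <- c("less_than_monthly", "monthly", "weekly", "daily")

episode_table <- function(sample3, scheme) {
  cnt <- code_count_category(sample3$duic_count_category,
                             sample3$duic_count_exact)
  al <- allocate_episodes(cnt, sample3$couse_category, scheme)
  al$freq_group <- factor(as.character(sample3$cannabis_freq),
                          levels = freq_groups_s3)
  al
}

#' DUIC episode-burden decomposition by use frequency
#'
#' Sums estimated DUIC(-) and DUIC(+) episodes within cannabis-use frequency
#' groups and expresses each group's contribution as a share (percent) of the
#' respective episode total; the user-population shares are computed over all
#' past-year users without a medical-only prescription, not only DUIC
#' reporters.
#'
#' @param sample3 episode sample: past-year users reporting past-30-day DUIC
#'   with complete episode and co-use data (see [derive_samples()]).
#' @param users past-year cannabis users without medical-only prescription
#'   (population-share denominator).
#' @param scheme an [allocation_scheme()].
#' @return a `burden_table`: per-group `pop_share`, `minus_share`,
#'   `plus_share` (percent, each column summing to 100) plus attributes
#'   `totals` (episode totals and the overall DUIC(+) proportion).
#' @export
burden_decomposition <- function(sample3, users,
                                 scheme = allocation_scheme()) {
  al <- episode_table(sample3, scheme)
  tot_minus <- sum(al$minus); tot_plus <- sum(al$plus)
  tot <- sum(al$total)
  if (tot <= 0) abort2("zero total episodes: shares undefined",
                       "degenerate_share")
  ufreq <- factor(as.character(users$cannabis_freq), levels = freq_groups_s3)
  if (any(is.na(ufreq)))
    abort2("users table contains non-user frequency levels", "config")
  g_minus <- tapply(al$minus, al$freq_group, sum, default = 0)
  g_plus <- tapply(al$plus, al$freq_group, sum, default = 0)
  g_users <- table(ufreq)
  tab <- data.frame(
    freq_group = freq_groups_s3,
    pop_share = 100 * as.vector(g_users) / sum(g_users),
    minus_share = if (tot_minus > 0) 100 * as.vector(g_minus) / tot_minus
                  else rep(0, 4),
    plus_share = if (tot_plus > 0) 100 * as.vector(g_plus) / tot_plus
                 else rep(0, 4))
  structure(tab, class = c("burden_table", "data.frame"),
            totals = list(total = tot, minus = tot_minus, plus = tot_plus,
                          plus_proportion = 100 * tot_plus / tot,
                          n_respondents = nrow(sample3),
                          n_users = nrow(users)))
}

#' Episode totals of a burden table
#' @param x a `burden_table`.
#' @return list with `total`, `minus`, `plus`, `plus_proportion` (percent),
#'   `n_respondents`, `n_users`.
#' @export
burden_totals <- function(x) attr(x, "totals")

#' Bootstrap confidence intervals for the burden decomposition
#'
#' Respondents are resampled with replacement (episode sample and user
#' population independently, pooled across countries) and the full
#' decomposition is recomputed per resample; percentile intervals are
#' attached to every share column. Resamples with zero total episodes are
#' skipped and counted (warning if more than 1% are skipped).
#'
#' @param sample3,users,scheme as in [burden_decomposition()].
#' @param B number of resamples (default 2000).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return a `burden_table` with `*_lo` / `*_hi` columns and a
#'   `plus_proportion_ci` entry in its totals.
#' @export
bootstrap_burden <- function(sample3, users, scheme = allocation_scheme(),
                             B = 2000, seed = NULL, conf = 0.95) {
  stopifnot(B >= 1)
  point <- burden_decomposition(sample3, users, scheme)
  al <- episode_table(sample3, scheme)
  ufreq <- factor(as.character(users$cannabis_freq), levels = freq_groups_s3)
  set.seed(stage_seed(seed %||% 0, "bootstrap_burden"))
  n3 <- nrow(al); nu <- length(ufreq)
  draws <- array(NA_real_, dim = c(B, 4, 3))
  plus_prop <- numeric(B)
  skipped <- 0L
  for (b in seq_len(B)) {
    i3 <- sample.int(n3, n3, replace = TRUE)
    iu <- sample.int(nu, nu, replace = TRUE)
    ab <- al[i3, ]
    tot <- sum(ab$total)
    if (tot <= 0) { skipped <- skipped + 1L; plus_prop[b] <- NA; next }
    tm <- sum(ab$minus); tp <- sum(ab$plus)
    draws[b, , 1] <- 100 * as.vector(table(ufreq[iu])) / nu
    gm <- tapply(ab$minus, ab$freq_group, sum, default = 0)
    gp <- tapply(ab$plus, ab$freq_group, sum, default = 0)
    draws[b, , 2] <- if (tm > 0) 100 * as.vector(gm) / tm else NA
    draws[b, , 3] <- if (tp > 0) 100 * as.vector(gp) / tp else NA
    plus_prop[b] <- 100 * tp / tot
  }
  if (skipped > 0.01 * B)
    warning(sprintf("%d of %d bootstrap resamples had zero episodes and were skipped",
                    skipped, B))
  a <- (1 - conf) / 2
  qs <- function(v) stats::quantile(v, c(a, 1 - a), na.rm = TRUE,
                                    names = FALSE)
  for (j in seq_along(c("pop", "minus", "plus"))) {
    nm <- c("pop", "minus", "plus")[j]
    ci <- apply(draws[, , j, drop = FALSE], 2, qs)
    point[[paste0(nm, "_share_lo")]] <- ci[1, ]
    point[[paste0(nm, "_share_hi")]] <- ci[2, ]
  }
  tt <- attr(point, "totals")
  tt$plus_proportion_ci <- qs(plus_prop)
  tt$B <- B
  tt$skipped <- skipped
  attr(point, "totals") <- tt
  point
}

#' Burden decomposition under alternative allocation schemes
#'
#' Recomputes the decomposition for each scheme and reports, per scheme, the
#' ranking of frequency groups by DUIC(+) share for qualitative-stability
#' checks.
#'
#' @param sample3,users as in [burden_decomposition()].
#' @param schemes named list of [allocation_scheme()] objects (>= 1).
#' @return named list of `burden_table`s, each with a `plus_rank` attribute
#'   (group names in decreasing DUIC(+) share order).
#' @export
sensitivity_schemes <- function(sample3, users, schemes) {
  if (!length(schemes)) abort2("need at least one allocation scheme",
                               "config")
  out <- lapply(schemes, function(sc) {
    tb <- burden_decomposition(sample3, users, sc)
    attr(tb, "plus_rank") <- tb$freq_group[order(-tb$plus_share)]
    tb
  })
  names(out) <- names(schemes) %||% paste0("scheme", seq_along(schemes))
  out
}
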