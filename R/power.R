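#' Power-simulation design for the two-country, two-wave binary outcome
#'
#' Anchor prevalences fix three arms (control t0, control t1, intervention
#' t0); the intervention t1 prevalence under a hypothesised DiD odds ratio is
#' `plogis(qlogis(p_I0) + qlogis(p_C1) - qlogis(p_C0) + log(or))`, placing
#' the effect entirely on the intervention wave-1 arm on the logit scale so
#' the saturated-model interaction identifies it.
#'
#' @param n_control,n_intervention arm sizes, each `c(t0, t1)`.
#' @param p_control_t0,p_control_t1,p_intervention_t0 anchor prevalences in
#'   (0, 1).
#' @param alpha two-sided test level (default 0.05).
#' @param target_power target power for the MDE search (default 0.80).
#' @param nsim simulated datasets per power evaluation (>= 100).
#' @param or_bracket optional c(low, high) bracket for the MDE search.
#' @param seed integer seed.
#' @return a `power_design`.
#' @export
power_design <- function(n_control, n_intervention,
                         p_control_t0, p_control_t1, p_intervention_t0,
                         alpha = 0.05, target_power = 0.80, nsim = 2000,
                         or_bracket = NULL, seed = 1L) {
  ns <- c(n_control, n_intervention)
  check_count(ns, "arm sizes")
  ps <- c(p_control_t0, p_control_t1, p_intervention_t0)
  if (any(ps <= 0) || any(ps >= 1))
    abort2("anchor prevalences must lie in (0, 1)", "config")
  if (alpha <= 0 || alpha >= 1) abort2("alpha must be in (0, 1)", "config")
  if (target_power <= alpha || target_power >= 1)
    abort2("target power must be in (alpha, 1)", "config")
  if (nsim < 100) abort2("nsim must be at least 100", "config")
  structure(list(
    n = c(control_t0 = n_control[1], control_t1 = n_control[2],
          intervention_t0 = n_intervention[1],
          intervention_t1 = n_intervention[2]),
    p_control_t0 = p_control_t0, p_control_t1 = p_control_t1,
    p_intervention_t0 = p_intervention_t0, alpha = alpha,
    target_power = target_power, nsim = nsim, or_bracket = or_bracket,
    seed = as.integer(seed)), class = "power_design")
}

arm_probs <- function(design, or_did) {
  p_i1 <- plogis(qlogis(design$p_intervention_t0) +
                   (qlogis(design$p_control_t1) -
                      qlogis(design$p_control_t0)) + log(or_did))
  c(control_t0 = design$p_control_t0, control_t1 = design$p_control_t1,
    intervention_t0 = design$p_intervention_t0, intervention_t1 = p_i1)
}

#' Simulate outcome counts for the four design arms
#'
#' Binomial draws per arm at the anchor prevalences, with the intervention
#' wave-1 prevalence implied by `or_did`.
#'
#' @param design a [power_design()].
#' @param or_did hypothesised DiD odds ratio.
#' @return data.frame with columns `arm`, `n`, `successes`, `p`.
#' @export
simulate_arm_counts <- function(design, or_did) {
  p <- arm_probs(design, or_did)
  if (any(p <= 0) || any(p >= 1))
    abort2("implied arm prevalence outside (0, 1)", "config")
  data.frame(arm = names(design$n), n = unname(design$n),
             successes = stats::rbinom(4, unname(design$n), unname(p)),
             p = unname(p))
}

#' Monte-Carlo power of the DiD interaction test
#'
#' Fraction of `nsim` simulated datasets whose saturated-model Wald test of
#' the time-by-country interaction rejects two-sided at `alpha`.
#' Non-converged or separated fits count conservatively as non-rejections
#' and are reported.
#'
#' @param design a [power_design()].
#' @param or_did hypothesised DiD odds ratio.
#' @param seed optional seed override (default: the design seed).
#' @return list with `power`, `mc_se` (= sqrt(p(1-p)/nsim)), `nsim`,
#'   `n_nonconverged`.
#' @export
estimate_power <- function(design, or_did, seed = NULL) {
  set.seed(stage_seed(seed %||% design$seed, "estimate_power"))
  rej <- 0L; bad <- 0L
  for (i in seq_len(design$nsim)) {
    arms <- simulate_arm_counts(design, or_did)
    p <- tryCatch(
      did_effect_counts(arms$successes, arms$n)$p_value,
      cannadid_error = function(e) NA_real_)
    if (is.na(p)) bad <- bad + 1L
    else if (p < design$alpha) rej <- rej + 1L
  }
  ph <- rej / design$nsim
  list(power = ph, mc_se = sqrt(ph * (1 - ph) / design$nsim),
       nsim = design$nsim, n_nonconverged = bad)
}

#' Analytic minimum detectable effect (Wald approximation)
#'
#' `MDE = exp((z_(1-alpha/2) + z_power) * SE_logOR)` with
#' `SE_logOR^2 = sum_arms 1 / (n p (1 - p))`, the fourth arm prevalence being
#' the null-projected intervention wave-1 value.
#'
#' @param design a [power_design()].
#' @return odds ratio.
#' @export
analytic_mde <- function(design) {
  p <- arm_probs(design, 1)
  se <- sqrt(sum(1 / (design$n * p * (1 - p))))
  exp((stats::qnorm(1 - design$alpha / 2) +
         stats::qnorm(design$target_power)) * se)
}

#' Minimum detectable DiD effect by Monte-Carlo bisection
#'
#' Brackets the target power and bisects on log odds ratio. At each midpoint
#' the power is estimated by simulation; bisection continues while the
#' +/- 2 MC-SE interval of the estimate excludes the target (so the step
#' direction is confident) and stops when it no longer does or when the
#' bracket is narrower than 0.01 in log-OR. Returns the bracket midpoint
#' alongside the analytic Wald approximation and the evaluated power curve.
#'
#' @param design a [power_design()]; `or_bracket` defaults to
#'   (0.72, 1.4) times the analytic MDE.
#' @return an `mde_result`: `mde_or`, `analytic_or`, `curve` (OR, power,
#'   MC SE, non-convergence count), `bracket`, `alpha`, `target_power`,
#'   `seed`.
#' @export
minimum_detectable_effect <- function(design) {
  analytic <- analytic_mde(design)
  br <- design$or_bracket %||% c(analytic * 0.72, analytic * 1.4)
  curve <- data.frame(or = numeric(0), power = numeric(0),
                      mc_se = numeric(0), n_nonconverged = integer(0))
  eval_pow <- function(or, tag) {
    est <- estimate_power(design, or, seed = design$seed + string_hash(tag))
    curve <<- rbind(curve, data.frame(or = or, power = est$power,
                                      mc_se = est$mc_se,
                                      n_nonconverged = est$n_nonconverged))
    est
  }
  lo <- log(br[1]); hi <- log(br[2])
  p_lo <- eval_pow(exp(lo), "lo")
  p_hi <- eval_pow(exp(hi), "hi")
  tp <- design$target_power
  if (p_lo$power > tp || p_hi$power < tp)
    abort2(sprintf(paste("power at bracket (%.3f, %.3f) does not straddle the",
                         "target %.2f; widen or_bracket"),
                   p_lo$power, p_hi$power, tp), "bracket")
  it <- 0L
  while (hi - lo > 0.01) {
    it <- it + 1L
    mid <- (lo + hi) / 2
    est <- eval_pow(exp(mid), paste0("bisect", it))
    if (est$power - 2 * est$mc_se > tp) hi <- mid
    else if (est$power + 2 * est$mc_se < tp) lo <- mid
    else break    # MC interval covers the target: cannot refine further
  }
  structure(list(mde_or = exp((lo + hi) / 2), analytic_or = analytic,
                 curve = curve[order(curve$or), ],
                 bracket = br, alpha = design$alpha,
                 target_power = design$target_power, seed = design$seed),
            class = "mde_result")
}

#' @export
print.mde_result <- function(x, ...) {
  cat(sprintf(
    "Minimum detectable DiD effect at %.0f%% power (alpha = %.2f): OR = %.3f\n",
    100 * x$target_power, x$alpha, x$mde_or))
  cat(sprintf("Analytic Wald approximation: OR = %.3f\n", x$analytic_or))
  print(transform(x$curve, power = round(power, 3), mc_se = round(mc_se, 4),
                  or = round(or, 3)), row.names = FALSE)
  invisible(x)
}
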