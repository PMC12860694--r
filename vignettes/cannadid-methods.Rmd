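---
title: "Evaluating cannabis legalisation with difference-in-differences survey models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating cannabis legalisation with difference-in-differences survey models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cannadid)
```

## The problem

When a country legalises recreational cannabis, two behavioural margins
matter for traffic safety: how many people use cannabis, and how often users
drive within two hours of using it (DUIC, driving under the influence of
cannabis). Neither can be judged from a single post-legalisation survey,
because secular trends move both quantities everywhere. The standard
quasi-experimental answer is difference-in-differences (DiD): survey an
intervention country and a comparable control country before and after the
policy change, and ask whether the change in the intervention country
differs from the change in the control.

`cannadid` implements that evaluation as a reusable, fully tested pipeline
over repeated cross-sectional survey microdata: a seeded synthetic survey
generator (respondent-level survey data of this kind are typically not
shareable), response-quality filtering, post-stratification weighting,
weighted logistic DiD models with Wald inference, covariate screening,
Monte-Carlo power analysis, and a bootstrap decomposition of DUIC episodes
into cannabis-only and polysubstance components.

## The model

For a binary outcome $Y$ (past-year cannabis use, or past-year DUIC among at
least monthly users), the DiD model is the logistic regression

$$\operatorname{logit} P(Y_i = 1) = \beta_0 + \beta_1\,\text{t}_1
  + \beta_2\,\text{intervention} + \beta_3\,(\text{t}_1 \times
  \text{intervention}) + \gamma^\top x_i,$$

with treatment coding and references $t_0$, control country, and the first
level of each covariate. $e^{\beta_3}$ is the DiD odds ratio: the factor by
which the intervention country's odds trend differs from the control trend.
A Wald 95% interval and two-sided p-value at $\alpha = 0.05$ accompany it;
two-sided because both an increase and a decrease of either outcome are
substantively meaningful. With no covariates the model is saturated and
$e^{\beta_3}$ equals the ratio of the two countries' before/after odds
ratios computed directly from the 2×2×2 counts — the package exploits this
identity both as a property test of the fitter and to run power simulations
on aggregated arms.

Fitting is by iteratively reweighted least squares on the weighted Bernoulli
likelihood with frequency-style case weights. Convergence is declared at a
maximum absolute coefficient change below $10^{-10}$ (at most 50
iterations); coefficients exceeding $|\beta| > 15$ raise a separation error,
and rank-deficient designs raise an aliasing error naming the offending
columns. Model fit is summarised by Nagelkerke's $R^2$ (Cox–Snell rescaled
by its attainable maximum) and collinearity by determinant-ratio
generalised variance inflation factors per term; the interaction's GVIF
exceeding 1 is expected, since an interaction is inherently correlated with
its main effects.

How standard errors should incorporate post-stratification weights is a
genuinely open choice; the package treats weights as case weights in the
likelihood and labels the resulting intervals model-based. A
survey-linearised (Taylor) variance is deliberately out of scope.

## Synthetic microdata: what it emulates, and what it does not

The generator reproduces the statistical structure the analysis relies on:

* two countries × two waves with configurable cell sizes, defaulting to the
  published design (intervention 6670/9692, control 2132/2102);
* past-year use prevalences anchored at 12.1% (intervention baseline) and
  9.4%/9.6% (control), with the intervention wave-1 prevalence derived on
  the logit scale as
  $\operatorname{logit} p_{I1} = \operatorname{logit} p_{I0} +
  [\operatorname{logit} p_{C1} - \operatorname{logit} p_{C0}] +
  \log \mathrm{OR}_{DiD}$, so the injected DiD odds ratio (default 1.18) is
  exactly what the saturated model estimates;
* quota covariates drawn independently from marginal distributions (the
  design quotas are marginal, so no joint grid is assumed);
* a five-level use-frequency item whose conditional distribution among
  users (41.3 / 20.3 / 18.4 / 20.0% for less-than-monthly / monthly /
  weekly / daily) matches the published user mix;
* DUIC among users at 13–29% depending on frequency, modulated on the logit
  scale by driver's-licence status (OR 2.0), female gender (OR 0.7) and a
  social-desirability score (OR 0.6 per SD) — the last so that the NQ−
  association check has a known truth;
* the instrument's filter change between waves: DUIC items are asked of at
  least monthly users at baseline but of all past-year users at follow-up
  (a per-wave ask threshold), and episode-count granularity exists at
  follow-up only;
* categorical 30-day episode counts with a truncated-geometric tail above
  15 (mean excess 10, capped at 60), consistent with a median of 2.5 and a
  printed maximum of 60;
* planted quality artifacts — speeders, zero-variability straightliners,
  failed control checks, cross-wave duplicate ids — at exact floor(rate×n)
  counts, with the truth retained in a ledger so the exclusion filters can
  be tested against it.

Values the study does not print (the 30-day-given-12-month DUIC rate of
0.45, the co-use mix 55/25/12/8%, artifact rates, the NQ− scale) were fixed
once at values a survey methodologist would call realistic and are plain
configuration fields, not tuned quantities.

The generator does **not** emulate panel recruitment, incentives,
attrition, item nonresponse beyond the instrument's skip logic, or real
correlation between quota covariates. Consequently, green tests demonstrate
that the estimators are correct and calibrated under the stated design —
they cannot demonstrate robustness to, e.g., informative nonresponse in
real fieldwork.

## Preprocessing

Exclusion filters run in a fixed order — cross-wave duplicate → speeder →
straightliner → control-check — and each removed row is attributed to the
first rule it violates, making the exclusion log deterministic and
permutation-stable. Respondents appearing in both waves are removed from
both. The actual thresholds behind "unrealistically short" response times
and "low variability" are instrument-specific; they are configuration
values (defaults: 180 s, variability index 0), not claims about any
particular fielding.

Three analytic samples follow: Sample 1 (everyone; the use model), Sample 2
(at least monthly users without medical-only prescription use, both waves —
the baseline inclusion rule applied at follow-up too, for comparability),
and Sample 3 (past-year users reporting past-30-day DUIC with complete
episode and co-use data; effectively post-legalisation, since episode
granularity exists only at follow-up). Non-binary respondents (a fraction
of a percent) are reassigned to male/female by a seeded fair coin to avoid
empty cells, with the probability configurable.

## Weighting

Post-stratification targets are the joint age × gender × education × region
distribution per country. Cell weighting (target share / sample share) is
exact but fails when an occupied target cell is empty in the sample, which
is common at quota-sample sizes over 96 cells; raking (iterative
proportional fitting over the four marginals, tolerance $10^{-8}$, max 100
sweeps) is therefore the pipeline default, and the degenerate-cell error in
cell mode recommends it. Weights are renormalised to mean 1 within each
(country, wave) so weighted totals equal sample sizes; no trimming is
applied by default. Diagnostics report the weight range, Kish effective
sample size $(\sum w)^2 / \sum w^2$ and design effect
$n \sum w^2 / (\sum w)^2$.

Contingency tests on weighted counts use a first-order Rao–Scott
correction: the Pearson statistic on the weighted table rescaled to $n$,
divided by the Kish design effect. Full linearisation is not implemented;
the first-order correction is the standard, fully testable choice for
post-stratified quota samples.

## Power and the minimum detectable effect

Because a null DiD can always reflect low power rather than no effect, the
pipeline estimates the minimum detectable effect (MDE): the smallest DiD
odds ratio the design would detect with 80% power at $\alpha = 0.05$. Arm
outcomes are simulated as binomials at the anchor prevalences with the
effect placed entirely on the intervention wave-1 arm (the same logit
parameterisation as the generator), each dataset is fitted saturated, and
power is the Wald rejection fraction; non-converged or separated fits count
conservatively as non-rejections. The MDE is found by bisection on log-OR,
stepping only while the ±2 MC-SE interval of the estimated power excludes
the 80% target, and stopping otherwise or at a bracket width of 0.01 in
log-OR; 2000 simulations per evaluation put the per-evaluation power SE
near 0.009. The analytic Wald approximation
$\mathrm{MDE} = \exp[(z_{1-\alpha/2} + z_{\mathrm{power}})\,
\mathrm{SE}_{\log OR}]$ with
$\mathrm{SE}^2_{\log OR} = \sum_{\text{arms}} 1/(n p (1-p))$ serves as a
cross-check; at the published designs it gives 1.38 (general population)
and 3.54 (monthly users), with the simulated values expected near the
published 1.40 and 3.68. The Wald test is the default; the study's own
simulation test statistic is not documented, and likelihood-ratio or score
variants would be straightforward extensions.

## Episode burden

The co-use item is categorical ("cannabis only", co-used "occasionally",
"mostly", "always"), not per episode, so episode counts are split
proportionally: 100/75/25/0% of a respondent's episodes count as
cannabis-only DUIC(−) under the primary scheme, the remainder as
polysubstance DUIC(+). Interval categories become midpoints (once → 1,
2–3 → 2.5, 4–9 → 6.5, 10–15 → 12.5; the open category uses the exact entry).
The 4–9 → 6.5 and 10–15 → 12.5 values follow the same midpoint rule as the
one documented instance (2–3 → 2.5). Fractional episodes are retained —
allocation is proportional, not per-episode rounding. Group shares are
computed over the DUIC(−) and DUIC(+) totals separately, while the
user-population denominator is all past-year users without a medical-only
prescription, not only DUIC reporters. Percentile 95% intervals come from
resampling respondents with replacement (2000 resamples, pooled across
countries by default; the episode sample and the user population are
resampled independently). Alternative schemes for "occasionally"/"mostly"
probe whether the ranking of frequency groups — the qualitative finding —
is stable.

## Numerical and design choices

* **Seeding.** One global seed is fanned out to per-stage substreams by a
  deterministic hash of stable stage names, so enabling or disabling one
  pipeline stage never changes another stage's draws, and every output is a
  pure function of (config, seed).
* **Degenerate inputs.** Zero or unit anchor prevalences have no logit; the
  generator passes the baseline through unchanged (this only arises in
  degenerate test configurations). Zero-margin contingency tables, empty
  bootstrap strata, zero-episode decompositions and unbracketed MDE
  searches all raise classed errors rather than returning NaN.
* **Imputation of the unasked baseline subgroup.** For the total-population
  DUIC sensitivity model, baseline less-than-monthly users (not asked DUIC
  at baseline) are imputed from the follow-up rate: deterministically by
  largest-remainder rounding in stable id order, or stochastically with a
  seed. This assumes no change in that subgroup; results from the model are
  interpreted accordingly.
* **Ties and ordering.** Filter attribution order (duplicate → speeder →
  straightliner → control check) is fixed; largest-remainder rounding
  assigns imputed cases in id order; bisection uses the bracket midpoint.
* **Problem sizes.** The test suite exercises parameter recovery and
  calibration at reduced survey sizes (hundreds to a few thousand
  respondents per cell) and uses the aggregated-arm representation for
  repeated-fit studies (type-I error, power), which is exactly equivalent
  for saturated models and keeps the suite fast; the acceptance checks of
  the two MDE designs run at the full published sizes with 2000 simulations
  per power evaluation.

## Limitations

The pipeline's inference is model-based throughout: weighted-fit standard
errors ignore the weighting's randomness, bootstrap intervals are
percentile (not BCa), and the Rao–Scott correction is first-order. The
synthetic generator's independence assumptions (covariates independent of
each other and, aside from the modelled licence/gender/NQ− effects, of the
outcomes) make screening behave null by construction except where effects
are injected. None of these affect the estimator contracts the tests
verify, but analyses of real microdata should revisit them.
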