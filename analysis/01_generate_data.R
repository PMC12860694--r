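#!/usr/bin/env Rscript
# Stage 1 -- synthetic survey microdata.
#
# The study's respondent-level data are not public, so the whole workflow
# runs on a seeded synthetic survey with the published design: two countries
# (intervention/control), two waves, the printed cell sizes (6670/9692 and
# 2132/2102), past-year use prevalences 12.1% / 9.4% / 9.6% and an injected
# DiD odds ratio of 1.18 on the intervention country at wave t1. Quality
# artifacts (speeders, straightliners, failed control checks, cross-wave
# duplicates) are planted at realistic rates with a retained truth ledger.

library(cannadid)

seed <- 20260927
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

cfg <- generator_config(
  artifact_rates = c(speeder = 0.01, straightliner = 0.008,
                     control_fail = 0.005, duplicate = 0.004),
  seed = seed)

survey <- inject_artifacts(generate_survey(cfg), cfg)
write_survey(survey, "results/data/survey.csv")

cat(sprintf("Generated %d respondents (%d planted quality artifacts).\n",
            nrow(survey), nrow(planted_ledger(survey))))
cat(sprintf("Derived intervention t1 prevalence: %.4f (injected DiD OR %.2f)\n",
            intervention_t1_prevalence(cfg), cfg$or_did))
print(with(survey, table(country, wave)))
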