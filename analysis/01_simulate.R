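#!/usr/bin/env Rscript
# Generate the synthetic cohort every downstream stage analyzes:
# 29 wild-type and 25 duplication mice, recorded at P8 and P12, with
# linked qRT-PCR expression and two-session social scores. Writes the
# three tables plus the ground-truth parameters under results/cohort/.

suppressPackageStartupMessages(library(vocalpredict))

cfg <- pipeline_config(rng_seed = 2026)
coh <- simulate_cohort(cfg)

out <- "results/cohort"
write_results(list(calls = coh$calls,
                   expression = coh$expression,
                   scores = coh$scores), out, cfg)
jsonlite::write_json(
  list(seed = cfg$rng_seed,
       behavior = coh$truth$behavior,
       panel = coh$truth$panel),
  file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA,
  force = TRUE)

cat("Cohort:", length(unique(coh$calls$pup_id)), "mice,",
    nrow(coh$calls), "calls over",
    nrow(unique(coh$calls[, c("pup_id", "age_day")])), "sessions;",
    nrow(coh$expression), "expression rows;",
    nrow(coh$scores), "social scores.\n")
cat("Planted score predictors:",
    paste(names(coh$truth$behavior$beta), collapse = ", "), "\n")
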