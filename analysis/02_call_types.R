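#!/usr/bin/env Rscript
# Per-pup call-type counts and proportions, group summaries, and the
# Mann-Whitney genotype comparisons with Benjamini-Hochberg decisions.

suppressPackageStartupMessages(library(vocalpredict))

cfg <- pipeline_config(rng_seed = 2026)
calls <- read_call_table("results/cohort/calls.csv", cfg)
calls <- classify_calls(calls, cfg)

prof <- profile_calls(calls, cfg)
summ <- profile_summary(prof, cfg)
tests <- calltype_genotype_tests(prof, cfg)

write_results(list(call_profiles = prof,
                   call_type_summary = summ,
                   call_type_tests = tests),
              "results/call_types", cfg)

sig <- tests[tests$significant, c("age_day", "measure", "call_type")]
cat("Call types differing between genotypes after FDR control:\n")
print(sig, row.names = FALSE)
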