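#!/usr/bin/env Rscript
# Two-call connections: group-level transition counts, proportions,
# Markov probabilities with chance-multiple display tiers, and the
# representative pup of each genotype at P12.

suppressPackageStartupMessages(library(vocalpredict))

cfg <- pipeline_config(rng_seed = 2026)
seg <- read_call_table("results/cohort/calls.csv", cfg)
im <- read.csv("results/sequences/interval_model.csv")
seg <- segment_calls(seg, im)

bundle <- list()
for (g in c("WT", "Dup")) for (a in c(8, 12)) {
  grp <- seg[seg$genotype == g & seg$age_day == a, ]
  tm <- transition_model(grp, cfg)
  tiers <- assign_tiers(tm, cfg$tier_multipliers, K = 13)
  key <- paste0(tolower(g), "_P", a)
  bundle[[paste0("markov_", key)]] <-
    data.frame(from = rownames(tm$P), tm$P, check.names = FALSE)
  bundle[[paste0("tiers_", key)]] <-
    data.frame(from = rownames(tiers), tiers, check.names = FALSE)
  n_tiered <- sum(tiers != "none")
  cat(sprintf("%-3s P%-2d: %d connections, %d above chance tiers\n",
              g, a, tm$n_connections, n_tiered))
}

for (g in c("WT", "Dup")) {
  pf <- pup_features_table(seg[seg$genotype == g, ], cfg, age = 12)
  rep <- select_representative(pf)
  cat("Representative", g, "pup at P12:", rep$pup_id, "\n")
  bundle[[paste0("features_p12_", tolower(g))]] <- pf
}

write_results(bundle, "results/transitions", cfg)
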