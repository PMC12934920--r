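#!/usr/bin/env Rscript
# Predictor selection: pool P12 call features with prefrontal-cortex
# gene RQs, run Lasso with AIC-based model choice per genotype x
# session, validate by 5-repeat subsample stability and per-gene
# correlations.

suppressPackageStartupMessages(library(vocalpredict))

cfg <- pipeline_config(rng_seed = 2026)
calls <- read_call_table("results/cohort/calls.csv", cfg)
im <- read.csv("results/sequences/interval_model.csv")
scores <- read.csv("results/cohort/scores.csv")
rq <- compute_rq(read.csv("results/cohort/expression.csv"), "WT")
seg <- segment_calls(calls, im)

genes <- unique(rq$gene)
bundle <- list()
for (g in c("WT", "Dup")) {
  pf <- pup_features_table(seg[seg$genotype == g, ], cfg, age = 12)
  for (s in 1:2) {
    fm <- build_feature_matrix(pf, rq, scores, g, s)
    sel <- lasso_aic(fm)
    st <- stability_selection(fm, seed = cfg$rng_seed + 100 * s +
                                (g == "Dup"))
    cv <- correlation_validation(fm, features = genes)
    key <- paste0(tolower(g), "_s", s)
    bundle[[paste0("path_", key)]] <-
      data.frame(lambda = sel$lambda, df = sel$df, r2 = sel$r2,
                 aic = sel$aic)
    bundle[[paste0("selected_", key)]] <-
      data.frame(feature = names(sel$selected),
                 coefficient = unname(sel$selected))
    bundle[[paste0("stability_", key)]] <-
      data.frame(feature = names(st$counts),
                 count = unname(st$counts),
                 stable = names(st$counts) %in% st$stable)
    bundle[[paste0("gene_correlations_", key)]] <- cv
    cat(sprintf("%-3s session %d: %2d selected; stable: %s\n", g, s,
                length(sel$selected),
                if (length(st$stable)) paste(st$stable, collapse = ", ")
                else "none"))
  }
}
write_results(bundle, "results/selection", cfg)

cat("\nGene correlations with Dup session-2 scores (top 3 by |r|):\n")
print(head(bundle$gene_correlations_dup_s2, 3), row.names = FALSE,
      digits = 3)
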