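#!/usr/bin/env Rscript
# Quantitative acoustic structure: UMAP embedding of the 7 acoustic
# features, density clustering, per-cluster call-type composition,
# genotype x age call counts per cluster, and cluster-level sequence
# trajectories. A random subsample keeps the embedding tractable.

suppressPackageStartupMessages(library(vocalpredict))

cfg <- pipeline_config(rng_seed = 2026)
calls <- read_call_table("results/cohort/calls.csv", cfg)
im <- read.csv("results/sequences/interval_model.csv")

set.seed(cfg$rng_seed)
idx <- sort(sample(nrow(calls), min(4000, nrow(calls))))
sub <- calls[idx, ]

er <- embed_calls(sub, cfg, seed = cfg$rng_seed)
cat("Embedded", nrow(sub), "calls into", er$n_clusters, "clusters (",
    sum(er$cluster == 0), "noise points).\n")

cc <- cluster_composition(sub, er, cfg)
sub$cluster <- er$cluster

# within-sequence trajectories across acoustic clusters, per genotype
# (adjacency is within the embedded subsample, a thinned view of the
# full sequences)
seg <- segment_calls(sub[sub$cluster > 0, ], im)
traj <- list()
for (g in c("WT", "Dup")) {
  M <- cluster_trajectories(seg[seg$genotype == g, ], k = er$n_clusters)
  traj[[g]] <- M
  cat(g, "within-cluster transition share:",
      round(sum(diag(M)) / sum(M), 3), "\n")
}

emb <- data.frame(pup_id = sub$pup_id, age_day = sub$age_day,
                  genotype = sub$genotype, call_type = sub$call_type,
                  x = er$embedding[, 1], y = er$embedding[, 2],
                  cluster = er$cluster)
write_results(list(
  embedding = emb,
  cluster_composition = data.frame(cluster = rownames(cc$composition),
                                   cc$composition, check.names = FALSE),
  cluster_counts = cc$counts,
  trajectories_wt = data.frame(from = rownames(traj$WT), traj$WT,
                               check.names = FALSE),
  trajectories_dup = data.frame(from = rownames(traj$Dup), traj$Dup,
                                check.names = FALSE)),
  "results/embedding", cfg)
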