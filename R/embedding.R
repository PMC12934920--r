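#' Acoustic feature columns used for embedding
#' @return Character vector of the 7 quantitative acoustic features.
#' @export
acoustic_feature_columns <- function() {
  c("bandwidth_hz", "freq_max_hz", "freq_mean_hz", "freq_min_hz",
    "intensity_max_db", "intensity_mean_db", "intensity_min_db")
}

# Minimal DBSCAN on a coordinate matrix. Plain O(n^2) neighbor search;
# intended for embeddings of up to a few tens of thousands of points.
# Returns integer labels, 0 = noise.
dbscan_labels <- function(X, eps, min_pts) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  nbr <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(nbr, length, 0L) >= min_pts
  labels <- integer(n)          # 0 = unassigned / noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nbr[[i]]
    while (length(queue)) {
      j <- queue[1]
      queue <- queue[-1]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) queue <- c(queue, nbr[[j]][labels[nbr[[j]]] == 0L])
      }
    }
  }
  labels
}

# eps heuristic: a high quantile of the min_pts-th nearest-neighbor
# distance; separates well-detached UMAP clusters without tuning.
eps_heuristic <- function(X, min_pts) {
  D <- as.matrix(stats::dist(X))
  kd <- apply(D, 1, function(d) sort(d)[min_pts + 1L])
  2 * stats::quantile(kd, 0.95, names = FALSE)
}

#' Embed calls by UMAP and cluster the embedding
#'
#' Z-scores the 7 acoustic features column-wise (Hz and dB scales are
#' incommensurate), embeds them with UMAP, and labels the embedding
#' either by a density-based scan (default; label 0 = noise) or by
#' k-means with silhouette-selected k.
#'
#' @param table Call table (or any data.frame with the acoustic
#'   columns).
#' @param config A [pipeline_config()].
#' @param seed Integer seed; the embedding is deterministic given it.
#' @param n_neighbors,min_dist,n_components UMAP parameters.
#' @param method `"dbscan"` or `"kmeans"`.
#' @param eps,min_pts Density-scan parameters; `eps = NULL` uses a
#'   nearest-neighbor-distance heuristic.
#' @param k_range Candidate k for the k-means alternative.
#' @return List of class `embedding_result`: `embedding` (matrix),
#'   `cluster` (integer per call), `n_clusters`, `params`.
#' @export
embed_calls <- function(table, config = pipeline_config(), seed = 1L,
                        n_neighbors = 15, min_dist = 0.1,
                        n_components = 2,
                        method = c("dbscan", "kmeans"),
                        eps = NULL, min_pts = 10, k_range = 2:8) {
  method <- match.arg(method)
  cols <- acoustic_feature_columns()
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols))
    stop("missing acoustic column(s): ",
         paste(missing_cols, collapse = ", "))
  X <- as.matrix(table[, cols])
  if (nrow(X) < n_neighbors)
    stop("need at least n_neighbors = ", n_neighbors, " calls")
  Z <- scale(X)
  Z[, attr(Z, "scaled:scale") == 0] <- 0
  set.seed(seed)
  emb <- uwot::umap(Z, n_neighbors = n_neighbors, min_dist = min_dist,
                    n_components = n_components, seed = seed,
                    n_threads = 1, n_sgd_threads = 1)
  if (method == "dbscan") {
    if (is.null(eps)) eps <- eps_heuristic(emb, min_pts)
    labels <- dbscan_labels(emb, eps, min_pts)
  } else {
    best <- NULL
    best_sil <- -Inf
    d <- stats::dist(emb)
    for (k in k_range) {
      km <- stats::kmeans(emb, centers = k, nstart = 5)
      sil <- mean(cluster::silhouette(km$cluster, d)[, "sil_width"])
      if (sil > best_sil) {
        best_sil <- sil
        best <- km$cluster
      }
    }
    labels <- best
  }
  structure(list(embedding = emb, cluster = as.integer(labels),
                 n_clusters = length(setdiff(unique(labels), 0L)),
                 params = list(seed = seed, n_neighbors = n_neighbors,
                               min_dist = min_dist,
                               n_components = n_components,
                               method = method, eps = eps,
                               min_pts = min_pts)),
            class = "embedding_result")
}

#' Per-cluster call-type composition and genotype densities
#'
#' @param table The call table that was embedded (same row order), with
#'   `call_type` and optionally `genotype` / `age_day`.
#' @param result An `embedding_result` from [embed_calls()].
#' @param config A [pipeline_config()].
#' @return List: `composition` (cluster x type proportion matrix, rows
#'   sum to 1), `counts` (long data.frame of per genotype x age x
#'   cluster call counts, if genotype present).
#' @export
cluster_composition <- function(table, result,
                                config = pipeline_config()) {
  stopifnot(nrow(table) == length(result$cluster))
  cl <- result$cluster
  keep <- cl > 0
  comp <- table(cluster = cl[keep],
                call_type = factor(table$call_type[keep],
                                   levels = config$alphabet))
  comp <- sweep(unclass(comp), 1, rowSums(comp), "/")
  counts <- NULL
  if (all(c("genotype", "age_day") %in% names(table))) {
    counts <- as.data.frame(table(genotype = table$genotype[keep],
                                  age_day = table$age_day[keep],
                                  cluster = cl[keep]))
    names(counts)[4] <- "n_calls"
  }
  list(composition = comp, counts = counts)
}
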