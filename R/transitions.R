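#' Two-call transition model
#'
#' Counts within-sequence adjacent call pairs over the rows given
#' (pool across pups for a group-level model, or pass one pup's rows
#' for a per-pup model) and derives the connection-proportion matrix Q
#' (counts / total connections) and the Markov matrix P (rows
#' normalized: probability of the next type given the current type).
#' Rows of P with no outgoing connection are left `NA` and listed in
#' `empty_rows` rather than propagated as NaN.
#'
#' @param table Segmented, labeled call table rows.
#' @param config A [pipeline_config()].
#' @return List of class `transition_model`: `C`, `Q`, `P` (13 x 13,
#'   dimnames = alphabet), `empty_rows`, `n_connections`.
#' @export
transition_model <- function(table, config = pipeline_config()) {
  al <- config$alphabet
  stopifnot(all(c("call_type", "sequence_id") %in% names(table)))
  sessions <- split(table, interaction(table$pup_id, table$age_day,
                                       drop = TRUE))
  from <- to <- character(0)
  for (s in sessions) for (sq in split(s$call_type, s$sequence_id)) {
    n <- length(sq)
    if (n < 2) next
    from <- c(from, sq[-n])
    to <- c(to, sq[-1])
  }
  C <- unclass(base::table(factor(from, levels = al),
                           factor(to, levels = al)))
  dimnames(C) <- list(al, al)
  total <- sum(C)
  if (total == 0) stop("no two-call connection in the given calls")
  Q <- C / total
  rs <- rowSums(C)
  P <- C / ifelse(rs > 0, rs, NA_real_)
  structure(list(C = C, Q = Q, P = P,
                 empty_rows = al[rs == 0], n_connections = total),
            class = "transition_model")
}

#' Chance-multiple display tiers for Markov probabilities
#'
#' A transition is tiered by how far its Markov probability exceeds
#' multiples of the chance level 1/K (K = alphabet size): the tier is
#' the highest multiplier m with P > m/K (strict). With the default
#' multipliers 1.5 / 2.0 / 2.5 and K = 13 the thresholds are 0.1154
#' (grey), 0.1538 (light brown) and 0.1923 (dark brown).
#'
#' @param model A [transition_model()] (or a plain probability matrix).
#' @param multipliers Ascending chance multiples.
#' @param K Alphabet size.
#' @return Character matrix over
#'   `{none, grey, light_brown, dark_brown}` (first three tier names
#'   are used for up to three multipliers; more get `tier4`, ...).
#' @export
assign_tiers <- function(model, multipliers = c(1.5, 2.0, 2.5), K = 13) {
  if (K <= 0) stop("K must be > 0")
  P <- if (inherits(model, "transition_model")) model$P else model
  multipliers <- sort(multipliers)
  tier_names <- c("grey", "light_brown", "dark_brown",
                  paste0("tier", seq_len(max(0, length(multipliers) - 3)) + 3))
  tier_names <- tier_names[seq_along(multipliers)]
  out <- matrix("none", nrow(P), ncol(P), dimnames = dimnames(P))
  for (m in seq_along(multipliers)) {
    hit <- !is.na(P) & P > multipliers[m] / K
    out[hit] <- tier_names[m]
  }
  out
}

#' Tier thresholds themselves
#'
#' @param multipliers Chance multiples.
#' @param K Alphabet size.
#' @return Named numeric vector of thresholds m / K.
#' @export
tier_thresholds <- function(multipliers = c(1.5, 2.0, 2.5), K = 13) {
  if (K <= 0) stop("K must be > 0")
  stats::setNames(multipliers / K, paste0("x", multipliers))
}

#' Full named feature vector of one pup
#'
#' Concatenates, with the naming convention used for predictor
#' selection, the 13 per-type counts `X(N)` and proportions `X(P)`,
#' the 169 pair counts `X_Y(N)` and pair proportions `X_Y(P)`, and the
#' 169 Markov probabilities `X_Y(MP)` (533 features). Absent pairs get
#' 0 for N and P; Markov probabilities from an empty row (the pup never
#' emitted the first type inside a sequence with a successor) are `NA`.
#'
#' @param session Segmented, labeled call-table rows of one pup session.
#' @param config A [pipeline_config()].
#' @return Named numeric vector of length 533.
#' @export
pup_features <- function(session, config = pipeline_config()) {
  al <- config$alphabet
  cnt <- table(factor(session$call_type, levels = al))
  n <- sum(cnt)
  props <- if (n > 0) as.numeric(cnt) / n else rep(NA_real_, length(al))
  pairs <- as.vector(outer(al, al, function(a, b) paste0(a, "_", b)))
  C <- matrix(0, length(al), length(al), dimnames = list(al, al))
  P <- matrix(NA_real_, length(al), length(al), dimnames = list(al, al))
  has_conn <- FALSE
  if (nrow(session) >= 2) {
    tm <- tryCatch(transition_model(session, config), error = function(e) NULL)
    if (!is.null(tm)) {
      C <- tm$C
      P <- tm$P
      has_conn <- TRUE
    }
  }
  Q <- if (has_conn) C / sum(C) else C          # pair proportions; 0 if none
  v <- c(stats::setNames(as.numeric(cnt), paste0(al, "(N)")),
         stats::setNames(props, paste0(al, "(P)")),
         stats::setNames(as.vector(C), paste0(pairs, "(N)")),
         stats::setNames(as.vector(Q), paste0(pairs, "(P)")),
         stats::setNames(as.vector(P), paste0(pairs, "(MP)")))
  v
}

#' Feature vectors for every pup at one age
#'
#' @param table Segmented, labeled call table.
#' @param config A [pipeline_config()].
#' @param age Age (day) to extract; `NULL` keeps all rows.
#' @return Data.frame: pup_id (+ genotype) and the 533 feature columns.
#' @export
pup_features_table <- function(table, config = pipeline_config(),
                               age = NULL) {
  if (!is.null(age)) table <- table[table$age_day == age, , drop = FALSE]
  parts <- split(table, factor(table$pup_id,
                               levels = unique(table$pup_id)))
  feats <- t(vapply(parts, pup_features, numeric(533), config = config))
  out <- data.frame(pup_id = names(parts), check.names = FALSE)
  if ("genotype" %in% names(table))
    out$genotype <- vapply(parts, function(s) as.character(s$genotype[1]), "")
  cbind(out, as.data.frame(feats, check.names = FALSE))
}

#' Select the representative pup of a group
#'
#' Scores each pup by its proximity to the group median over four
#' feature blocks — per-type counts, per-type proportions, pair counts
#' and pair proportions (Markov probabilities deliberately excluded) —
#' after z-scoring each feature within the group. The pup minimizing
#' the summed per-block Euclidean distances to the block median vectors
#' is returned; ties go to the lowest pup_id.
#'
#' @param features Output of [pup_features_table()] for one group.
#' @return List: `pup_id`, `distances` (named per pup).
#' @export
select_representative <- function(features) {
  if (!nrow(features)) stop("empty group")
  ids <- as.character(features$pup_id)
  fcols <- setdiff(names(features), c("pup_id", "genotype"))
  is_pair <- grepl("_", fcols, fixed = TRUE)
  blocks <- list(
    type_counts = fcols[!is_pair & endsWith(fcols, "(N)")],
    type_props  = fcols[!is_pair & endsWith(fcols, "(P)")],
    pair_counts = fcols[is_pair & endsWith(fcols, "(N)")],
    pair_props  = fcols[is_pair & endsWith(fcols, "(P)")])
  dist_total <- stats::setNames(numeric(length(ids)), ids)
  for (cols in blocks) {
    X <- as.matrix(features[, cols, drop = FALSE])
    mu <- colMeans(X, na.rm = TRUE)
    sdv <- apply(X, 2, stats::sd, na.rm = TRUE)
    keep <- !is.na(sdv) & sdv > 0
    if (!any(keep)) next
    Z <- sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep],
               "/")
    med <- apply(Z, 2, stats::median, na.rm = TRUE)
    dist_total <- dist_total +
      sqrt(rowSums(sweep(Z, 2, med)^2, na.rm = TRUE))
  }
  ord <- order(dist_total, ids)
  list(pup_id = ids[ord[1]], distances = dist_total)
}

#' Acoustic-cluster transition counts along sequences
#'
#' Counts within-sequence adjacent transitions between acoustic-cluster
#' labels (rather than call types), summarizing how call trajectories
#' move through the embedding space.
#'
#' @param table Segmented call table with a `cluster` column.
#' @param k Number of clusters; defaults to the largest label present.
#' @return k x k integer count matrix.
#' @export
cluster_trajectories <- function(table, k = NULL) {
  stopifnot(all(c("cluster", "sequence_id") %in% names(table)))
  bad <- which(is.na(table$cluster))
  if (length(bad))
    stop("unlabeled calls at rows: ",
         paste(utils::head(bad, 10), collapse = ", "))
  labs <- as.integer(table$cluster)
  if (is.null(k)) k <- max(labs)
  M <- matrix(0L, k, k, dimnames = list(seq_len(k), seq_len(k)))
  sessions <- split(seq_len(nrow(table)),
                    interaction(table$pup_id, table$age_day, drop = TRUE))
  for (idx in sessions) for (sq in split(labs[idx],
                                         table$sequence_id[idx])) {
    n <- length(sq)
    if (n < 2) next
    for (i in seq_len(n - 1L))
      M[sq[i], sq[i + 1L]] <- M[sq[i], sq[i + 1L]] + 1L
  }
  M
}
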