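#' Inter-call intervals of one session
#'
#' The silent gap between consecutive calls: next onset minus previous
#' offset (onset + duration), in ms. One fewer interval than calls.
#'
#' @param session Call-table rows of a single (pup, age) session, in
#'   onset order.
#' @return Numeric vector of gaps (ms); length 0 for < 2 calls.
#' @export
call_intervals <- function(session) {
  n <- nrow(session)
  if (n < 2) return(numeric(0))
  offset_s <- session$onset_s + session$duration_ms / 1000
  (session$onset_s[-1] - offset_s[-n]) * 1000
}

#' Locate the observed-vs-theoretical interval density crossing
#'
#' The sequence threshold is the smallest t > 0 where the Gaussian-KDE
#' density of the observed inter-call intervals drops below the
#' exponential density `lambda * exp(-lambda t)` expected if the same
#' number of calls were emitted as a Poisson process over the recording
#' period. The sign change (positive to negative difference) is found
#' by scanning a grid and refined by bisection.
#'
#' @param intervals_ms Observed intervals, ms.
#' @param lambda Theoretical Poisson rate, calls per ms.
#' @param max_ms Upper end of the search range, ms.
#' @param grid_step_ms Scan grid step, ms.
#' @param tol_ms Bisection tolerance, ms.
#' @param bw Kernel bandwidth (ms); `NULL` = Silverman's rule.
#' @return List: `crossing_ms`, `lambda`, `bw`, `n_intervals`.
#' @export
interval_crossing <- function(intervals_ms, lambda, max_ms,
                              grid_step_ms = 1, tol_ms = 0.01,
                              bw = NULL) {
  if (length(intervals_ms) < 2) stop("need at least 2 intervals")
  if (lambda <= 0) stop("lambda must be > 0")
  if (is.null(bw)) bw <- stats::bw.nrd0(intervals_ms)
  gdiff <- function(t) {
    kde <- vapply(t, function(ti) mean(stats::dnorm(ti, intervals_ms, bw)), 0)
    kde - lambda * exp(-lambda * t)
  }
  grid <- seq(grid_step_ms, max_ms, by = grid_step_ms)
  # FFT-based KDE for the coarse scan (exact kernel sums would cost
  # grid x n); the bisection below re-evaluates the exact kernel sum
  kde_grid <- stats::density(intervals_ms, bw = bw, from = grid[1],
                             to = grid[length(grid)], n = length(grid))$y
  g <- kde_grid - lambda * exp(-lambda * grid)
  # first grid point where a previously-positive difference turns
  # negative; differences below tol (both densities negligible, e.g.
  # far tails) carry no sign information
  tol <- 1e-9 * lambda
  seen_pos <- FALSE
  cross_i <- NA_integer_
  for (i in seq_along(g)) {
    if (g[i] > tol) seen_pos <- TRUE
    else if (seen_pos && g[i] < -tol) { cross_i <- i; break }
  }
  if (is.na(cross_i))
    stop("no positive-to-negative crossing on (0, ", max_ms,
         "] ms; consider overriding the KDE bandwidth")
  lo <- grid[cross_i - 1L]
  hi <- grid[cross_i]
  while (hi - lo > tol_ms) {
    mid <- (lo + hi) / 2
    if (gdiff(mid) > 0) lo <- mid else hi <- mid
  }
  list(crossing_ms = (lo + hi) / 2, lambda = lambda, bw = bw,
       n_intervals = length(intervals_ms))
}

#' Fit the interval model per genotype x age group
#'
#' Pools inter-call intervals across all pups of each group, sets the
#' theoretical Poisson rate to total calls / total recording time, and
#' locates the density crossing that defines the group's sequence
#' threshold.
#'
#' @param table Validated call table with a `genotype` column.
#' @param config A [pipeline_config()]; `session_duration` gives the
#'   recording time per session.
#' @return Data.frame, one row per genotype x age: `n_calls`,
#'   `n_intervals`, `lambda_per_ms`, `bw_ms`, `crossing_ms`.
#' @export
fit_interval_model <- function(table, config = pipeline_config()) {
  stopifnot("genotype" %in% names(table))
  out <- list()
  for (g in sort(unique(table$genotype)))
    for (a in sort(unique(table$age_day))) {
      grp <- table[table$genotype == g & table$age_day == a, , drop = FALSE]
      if (!nrow(grp)) next
      sessions <- split(grp, interaction(grp$pup_id, grp$age_day,
                                         drop = TRUE))
      ivs <- unlist(lapply(sessions, call_intervals), use.names = FALSE)
      if (length(ivs) < 2)
        stop("group ", g, " x P", a, " has fewer than 2 intervals")
      lambda <- nrow(grp) /
        (length(sessions) * config$session_duration * 1000)
      cr <- interval_crossing(ivs, lambda,
                              max_ms = config$session_duration * 1000,
                              grid_step_ms = config$grid_step_ms,
                              tol_ms = config$bisect_tol_ms,
                              bw = config$kde_bw)
      out[[length(out) + 1L]] <- data.frame(
        genotype = g, age_day = a, n_calls = nrow(grp),
        n_intervals = cr$n_intervals, lambda_per_ms = lambda,
        bw_ms = cr$bw, crossing_ms = cr$crossing_ms)
    }
  do.call(rbind, out)
}

#' Segment one session into call sequences
#'
#' Splits the ordered calls of a session wherever the silent gap
#' reaches the threshold: the calls before and after such a gap end one
#' sequence and start the next. Gaps shorter than the threshold keep
#' calls within a sequence; singleton sequences are allowed.
#'
#' @param session Call-table rows of one session, onset-sorted.
#' @param crossing_ms Sequence threshold, ms.
#' @return `session` with an integer `sequence_id` column (1-based,
#'   session-local).
#' @export
segment_sequences <- function(session, crossing_ms) {
  if (crossing_ms <= 0) stop("crossing_ms must be > 0")
  n <- nrow(session)
  if (n == 0) {
    session$sequence_id <- integer(0)
    return(session)
  }
  gaps <- call_intervals(session)
  session$sequence_id <- c(1L, 1L + cumsum(as.integer(gaps >= crossing_ms)))
  session
}

#' Segment a whole call table using per-group thresholds
#'
#' @param table Validated call table with `genotype`.
#' @param interval_model Output of [fit_interval_model()], or a single
#'   numeric threshold applied to every session.
#' @return The table with a `sequence_id` column.
#' @export
segment_calls <- function(table, interval_model) {
  lookup <- function(g, a) {
    if (is.numeric(interval_model) && length(interval_model) == 1)
      return(interval_model)
    row <- interval_model$genotype == g & interval_model$age_day == a
    if (!any(row)) stop("no crossing for group ", g, " x P", a)
    interval_model$crossing_ms[row]
  }
  parts <- split(table, interaction(table$pup_id, table$age_day,
                                    drop = TRUE))
  parts <- lapply(parts, function(s)
    segment_sequences(s, lookup(s$genotype[1], s$age_day[1])))
  out <- do.call(rbind, parts)
  out <- out[order(out$pup_id, out$age_day, out$onset_s), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-pup sequence statistics
#'
#' @param table Segmented call table (with `sequence_id`).
#' @return Data.frame per pup x age: `n_sequences`,
#'   `mean_calls_per_sequence`, `mean_sequence_duration_ms` (last call
#'   offset minus first call onset within a sequence).
#' @export
sequence_stats <- function(table) {
  stopifnot("sequence_id" %in% names(table))
  parts <- split(table, interaction(table$pup_id, table$age_day,
                                    drop = TRUE))
  rows <- lapply(parts, function(s) {
    seqs <- split(s, s$sequence_id)
    lens <- vapply(seqs, nrow, 0L)
    durs <- vapply(seqs, function(q) {
      (q$onset_s[nrow(q)] + q$duration_ms[nrow(q)] / 1000 -
         q$onset_s[1]) * 1000
    }, 0)
    df <- data.frame(pup_id = s$pup_id[1], age_day = s$age_day[1],
                     n_sequences = length(seqs),
                     mean_calls_per_sequence = mean(lens),
                     mean_sequence_duration_ms = mean(durs))
    if ("genotype" %in% names(s)) df$genotype <- s$genotype[1]
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Shannon entropy (bits) of a count vector.
shannon_bits <- function(counts) {
  counts <- counts[counts > 0]
  if (!length(counts)) return(NA_real_)
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

# All within-sequence k-grams of a segmented session, as strings.
session_kgrams <- function(types, sequence_id, k) {
  out <- lapply(split(types, sequence_id), function(sq) {
    n <- length(sq)
    if (n < k) return(character(0))
    idx <- seq_len(n - k + 1L)
    cols <- lapply(seq_len(k) - 1L, function(j) sq[idx + j])
    do.call(paste, c(cols, sep = ">"))
  })
  unlist(out, use.names = FALSE)
}

#' Entropy profile H0-H4 per pup
#'
#' H0 is the log2 of the number of distinct call types the pup actually
#' emitted (its realized repertoire size); H1 the Shannon entropy of
#' its call-type distribution over all calls; H2-H4 the per-symbol
#' Shannon entropies of the empirical k-gram distributions (sliding
#' window, step 1) taken only within sequences, i.e. H(k-gram)/k.
#' Levels with no k-gram (all sequences shorter than k) are `NA`.
#'
#' @param table Segmented, labeled call table.
#' @param config A [pipeline_config()].
#' @param per_symbol If `FALSE`, report plain joint k-gram entropy
#'   instead of dividing by k.
#' @return Data.frame per pup x age with columns H0..H4.
#' @export
entropy_profile <- function(table, config = pipeline_config(),
                            per_symbol = TRUE) {
  stopifnot(all(c("call_type", "sequence_id") %in% names(table)))
  parts <- split(table, interaction(table$pup_id, table$age_day,
                                    drop = TRUE))
  rows <- lapply(parts, function(s) {
    if (!nrow(s)) return(NULL)
    H <- numeric(5)
    H[1] <- log2(length(unique(s$call_type)))
    H[2] <- shannon_bits(table(s$call_type))
    for (k in 2:4) {
      grams <- session_kgrams(s$call_type, s$sequence_id, k)
      H[k + 1L] <- if (!length(grams)) NA_real_
        else shannon_bits(table(grams)) / (if (per_symbol) k else 1)
    }
    df <- data.frame(pup_id = s$pup_id[1], age_day = s$age_day[1],
                     H0 = H[1], H1 = H[2], H2 = H[3], H3 = H[4],
                     H4 = H[5])
    if ("genotype" %in% names(s)) df$genotype <- s$genotype[1]
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
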