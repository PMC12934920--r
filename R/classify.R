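#' Classify one frequency contour into the 13-type taxonomy
#'
#' Deterministic decision tree over the call's principal frequency
#' contour. Precedence: a detected simultaneous harmonic component wins
#' (`Har`); very short calls are `Sh`; pitch jumps (discontinuities of
#' at least `jump_hz` within `jump_ms`) are counted and signed — one up
#' `Su`, one down `Sd`, exactly two `Ts`, three or more `Ms`; jump-free
#' contours with total excursion below `flat_hz` are `F`; monotone
#' contours are `U` / `D`; a single interior extremum whose rise and
#' fall both reach `chevron_hz` is `Ch` (maximum) or `RCh` (minimum);
#' two or more direction changes give `Cx`; anything left is `Amb`.
#'
#' @param contour Data.frame or matrix with columns `time_ms`
#'   (strictly increasing) and `frequency_hz`; at least 2 points.
#' @param thresholds Classifier thresholds, see [pipeline_config()].
#' @param harmonic `TRUE` if a simultaneous secondary component was
#'   detected upstream.
#' @return One label from [call_type_alphabet()].
#' @export
classify_call <- function(contour,
                          thresholds = pipeline_config()$thresholds,
                          harmonic = FALSE) {
  contour <- as.data.frame(contour)
  if (nrow(contour) < 2)
    stop("contour needs at least 2 points")
  t <- contour$time_ms
  f <- contour$frequency_hz
  if (any(diff(t) <= 0)) stop("contour times must be strictly increasing")

  if (isTRUE(harmonic)) return("Har")
  if ((t[length(t)] - t[1]) < thresholds$short_ms) return("Sh")

  df <- diff(f)
  dt <- diff(t)
  jump <- abs(df) >= thresholds$jump_hz & dt <= thresholds$jump_ms
  n_jump <- sum(jump)
  if (n_jump == 1) return(if (df[jump] > 0) "Su" else "Sd")
  if (n_jump == 2) return("Ts")
  if (n_jump >= 3) return("Ms")

  if ((max(f) - min(f)) < thresholds$flat_hz) return("F")
  if (all(df >= 0)) return("U")
  if (all(df <= 0)) return("D")

  s <- sign(df)
  s <- s[s != 0]
  flips <- sum(diff(s) != 0)
  if (flips >= 2) return("Cx")
  # exactly one direction change: single interior extremum
  if (s[1] > 0) {               # rise then fall
    rise <- max(f) - f[1]
    fall <- max(f) - f[length(f)]
    if (rise >= thresholds$chevron_hz && fall >= thresholds$chevron_hz)
      return("Ch")
  } else {                      # fall then rise
    fall <- f[1] - min(f)
    rise <- f[length(f)] - min(f)
    if (fall >= thresholds$chevron_hz && rise >= thresholds$chevron_hz)
      return("RCh")
  }
  "Amb"
}

#' Canonical contour fixtures, one per call type
#'
#' A small built-in suite of idealized contours that exercises every
#' branch of the classifier: under the default thresholds each element
#' classifies to its own name.
#'
#' @return Named list (names = the 13 labels); each element has
#'   `contour` (time_ms / frequency_hz data.frame) and `harmonic`.
#' @export
canonical_contours <- function() {
  mk <- function(t, f, harmonic = FALSE)
    list(contour = data.frame(time_ms = t, frequency_hz = f),
         harmonic = harmonic)
  k <- 1000
  list(
    Har = mk(c(0, 20, 40), c(60, 60, 60) * k, harmonic = TRUE),
    Su  = mk(c(0, 10, 20, 21, 30, 40), c(50, 50, 50, 65, 65, 65) * k),
    Ts  = mk(c(0, 10, 11, 20, 21, 30), c(50, 50, 65, 65, 80, 80) * k),
    Cx  = mk(c(0, 8, 16, 24, 32), c(60, 67, 59, 67, 60) * k),
    Sd  = mk(c(0, 10, 20, 21, 30, 40), c(65, 65, 65, 50, 50, 50) * k),
    Ms  = mk(c(0, 10, 11, 20, 21, 30, 31, 40),
             c(50, 50, 65, 65, 50, 50, 65, 65) * k),
    D   = mk(c(0, 8, 16, 24, 32, 40), c(75, 70, 65, 60, 55, 50) * k),
    Ch  = mk(c(0, 10, 20, 30, 40), c(55, 62, 69, 62, 55) * k),
    Sh  = mk(c(0, 4, 8), c(60, 60, 60) * k),
    F   = mk(c(0, 10, 20, 30, 40), c(60, 61, 60, 59, 60) * k),
    U   = mk(c(0, 8, 16, 24, 32, 40), c(50, 55, 60, 65, 70, 75) * k),
    RCh = mk(c(0, 10, 20, 30, 40), c(69, 62, 55, 62, 69) * k),
    Amb = mk(c(0, 10, 20, 30), c(55, 62, 69, 68) * k)
  )
}

# Parse "t1:f1;t2:f2;..." into a contour data.frame (ms, Hz).
parse_contour <- function(s) {
  pts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  data.frame(time_ms = vapply(pts, function(p) as.numeric(p[1]), 0),
             frequency_hz = vapply(pts, function(p) as.numeric(p[2]), 0))
}

# Serialize a contour data.frame back to the string form.
serialize_contour <- function(contour) {
  paste(sprintf("%g:%g", contour$time_ms, contour$frequency_hz),
        collapse = ";")
}

#' Classify every call in a table
#'
#' Rows carrying a serialized `contour` are classified from it; rows
#' without a contour keep their existing `call_type`. A row with
#' neither is an error.
#'
#' @param table A validated call table.
#' @param config A [pipeline_config()].
#' @return The table with `call_type` filled for every row.
#' @export
classify_calls <- function(table, config = pipeline_config()) {
  has_contour <- "contour" %in% names(table) & !is_blank(table[["contour"]])
  if (!"call_type" %in% names(table)) table$call_type <- NA_character_
  need <- which(has_contour)
  for (i in need) {
    table$call_type[i] <- classify_call(parse_contour(table$contour[i]),
                                        config$thresholds,
                                        harmonic = isTRUE(as.logical(
                                          table$harmonic_flag[i])))
  }
  bad <- which(is.na(table$call_type))
  if (length(bad))
    stop("rows without contour or call_type: ",
         paste(utils::head(bad, 5), collapse = ", "))
  unknown <- setdiff(unique(table$call_type), config$alphabet)
  if (length(unknown))
    stop("call_type label(s) outside the alphabet: ",
         paste(unknown, collapse = ", "))
  table
}

is_blank <- function(x) {
  if (is.null(x)) return(TRUE)
  is.na(x) | !nzchar(as.character(x))
}

#' Per-pup call-type counts and proportions
#'
#' Counts each of the 13 types per (pup, age) session and converts to
#' within-pup proportions. A session listed in `roster` but absent from
#' the table (a pup that emitted no call) gets all-zero counts,
#' undefined proportions and `excluded = TRUE`, mirroring the omission
#' of silent pups from proportion summaries.
#'
#' @param table Call table with `call_type` filled.
#' @param config A [pipeline_config()].
#' @param roster Optional data.frame (pup_id, age_day, genotype) of all
#'   intended sessions, so silent pups are represented.
#' @return Data.frame, one row per pup x age: `n_total`, `excluded`,
#'   count columns `n_<type>` and proportion columns `p_<type>`.
#' @export
profile_calls <- function(table, config = pipeline_config(),
                          roster = NULL) {
  al <- config$alphabet
  if (!"call_type" %in% names(table))
    table <- classify_calls(table, config)
  keys <- unique(table[, intersect(c("pup_id", "age_day", "genotype"),
                                   names(table)), drop = FALSE])
  if (!is.null(roster)) {
    keys <- merge(roster, keys, all = TRUE)
    keys <- keys[, intersect(c("pup_id", "age_day", "genotype"),
                             names(keys)), drop = FALSE]
    keys <- unique(keys)
  }
  keys <- keys[order(keys$pup_id, keys$age_day), , drop = FALSE]
  counts <- matrix(0L, nrow(keys), length(al),
                   dimnames = list(NULL, paste0("n_", al)))
  for (r in seq_len(nrow(keys))) {
    sel <- table$pup_id == keys$pup_id[r] & table$age_day == keys$age_day[r]
    tb <- table(factor(table$call_type[sel], levels = al))
    counts[r, ] <- as.integer(tb)
  }
  n_total <- rowSums(counts)
  props <- counts / ifelse(n_total > 0, n_total, NA_real_)
  colnames(props) <- paste0("p_", al)
  out <- cbind(keys,
               data.frame(n_total = n_total, excluded = n_total == 0),
               as.data.frame(counts), as.data.frame(props))
  rownames(out) <- NULL
  out
}

#' Group summaries of a call-type profile
#'
#' Mean and SEM of per-type counts and proportions per genotype x age.
#' Silent pups (excluded flag) contribute to count summaries but not to
#' proportion summaries.
#'
#' @param profile Output of [profile_calls()].
#' @param config A [pipeline_config()].
#' @return Long data.frame: genotype, age_day, call_type, measure
#'   (count / proportion), mean, sem, n.
#' @export
profile_summary <- function(profile, config = pipeline_config()) {
  al <- config$alphabet
  stopifnot("genotype" %in% names(profile))
  out <- list()
  for (g in unique(profile$genotype)) for (a in unique(profile$age_day)) {
    sub <- profile[profile$genotype == g & profile$age_day == a, ,
                   drop = FALSE]
    if (!nrow(sub)) next
    subp <- sub[!sub$excluded, , drop = FALSE]
    for (ty in al) {
      cn <- sub[[paste0("n_", ty)]]
      pn <- subp[[paste0("p_", ty)]]
      out[[length(out) + 1L]] <- data.frame(
        genotype = g, age_day = a, call_type = ty,
        measure = c("count", "proportion"),
        mean = c(mean(cn), mean(pn)),
        sem = c(stats::sd(cn) / sqrt(length(cn)),
                stats::sd(pn) / sqrt(length(pn))),
        n = c(length(cn), length(pn)))
    }
  }
  do.call(rbind, out)
}

#' Genotype comparisons of call-type counts and proportions
#'
#' Mann-Whitney U test per call type x age x measure between the two
#' genotypes (normal approximation with tie correction at these sample
#' sizes), Benjamini-Hochberg adjusted within each age x measure family.
#'
#' @param profile Output of [profile_calls()] with a `genotype` column.
#' @param config A [pipeline_config()]; first `fdr_levels` entry is the
#'   decision level.
#' @return Data.frame: age_day, measure, call_type, U, p, p_bh,
#'   significant.
#' @export
calltype_genotype_tests <- function(profile, config = pipeline_config()) {
  al <- config$alphabet
  gts <- sort(unique(profile$genotype))
  if (length(gts) != 2) stop("exactly two genotypes required")
  res <- list()
  for (a in unique(profile$age_day)) for (ms in c("count", "proportion")) {
    sub <- profile[profile$age_day == a, , drop = FALSE]
    if (ms == "proportion") sub <- sub[!sub$excluded, , drop = FALSE]
    pre <- if (ms == "count") "n_" else "p_"
    U <- p <- numeric(length(al))
    for (i in seq_along(al)) {
      x <- sub[[paste0(pre, al[i])]][sub$genotype == gts[1]]
      y <- sub[[paste0(pre, al[i])]][sub$genotype == gts[2]]
      wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                                correct = TRUE))
      U[i] <- unname(wt$statistic)
      p[i] <- wt$p.value
    }
    res[[length(res) + 1L]] <- data.frame(
      age_day = a, measure = ms, call_type = al, U = U, p = p,
      p_bh = bh_adjust(p)$p_adjusted)
  }
  out <- do.call(rbind, res)
  out$significant <- !is.na(out$p_bh) & out$p_bh <= config$fdr_levels[1]
  out
}
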