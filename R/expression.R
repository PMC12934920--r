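#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted p-values: with ordered p_(1) <= ... <= p_(m), adjusted
#' p_(i) = min over j >= i of m * p_(j) / j, capped at 1 — the step-up
#' procedure controlling the false discovery rate. Decisions at each
#' FDR level reject where the adjusted p is at or below the level.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` passed
#'   through).
#' @param m Number of tests; defaults to the number of non-`NA`
#'   p-values.
#' @param fdr_levels FDR levels for the decision matrix.
#' @return List: `p_adjusted` (input order), `decisions` (logical
#'   matrix, one column per FDR level).
#' @export
bh_adjust <- function(p, m = NULL, fdr_levels = c(0.05, 0.10, 0.25)) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]")
  if (is.null(m)) m <- sum(ok)
  adj <- rep(NA_real_, length(p))
  if (m > 0 && any(ok)) {
    ord <- order(p[ok])
    ps <- p[ok][ord]
    a <- pmin(1, m * ps / seq_along(ps))
    a <- rev(cummin(rev(a)))
    tmp <- numeric(sum(ok))
    tmp[ord] <- a
    adj[ok] <- tmp
  }
  dec <- vapply(fdr_levels, function(q) !is.na(adj) & adj <= q,
                logical(length(p)))
  dec <- matrix(dec, nrow = length(p),
                dimnames = list(NULL, paste0("fdr_", fdr_levels)))
  list(p_adjusted = adj, decisions = dec)
}

#' Relative quantification by the delta-delta-Ct method
#'
#' Per gene (and region, if present): `dCt = Ct_target - Ct_housekeeping`;
#' `ddCt = dCt - mean(dCt)` over the calibrator genotype;
#' `RQ = 2^(-ddCt)`. Calibrating on the arithmetic mean of dCt makes
#' the calibrator group's geometric-mean RQ exactly 1 for every gene.
#'
#' @param table Data.frame with columns `mouse_id`, `genotype`, `gene`,
#'   `ct_target`, `ct_housekeeping` (optional `region`).
#' @param calibrator_group Genotype label used as calibrator.
#' @return The table with `dct`, `ddct` and `rq` columns added.
#' @export
compute_rq <- function(table, calibrator_group = "WT") {
  need <- c("mouse_id", "genotype", "gene", "ct_target", "ct_housekeeping")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols))
    stop("expression table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!any(table$genotype == calibrator_group))
    stop("no rows for calibrator group '", calibrator_group, "'")
  table$dct <- table$ct_target - table$ct_housekeeping
  keycols <- intersect(c("gene", "region"), names(table))
  key <- interaction(table[keycols], drop = TRUE)
  table$ddct <- NA_real_
  for (k in levels(key)) {
    idx <- key == k
    cal <- idx & table$genotype == calibrator_group
    if (!any(cal)) stop("no calibrator rows for ", k)
    table$ddct[idx] <- table$dct[idx] - mean(table$dct[cal])
  }
  table$rq <- 2^(-table$ddct)
  table
}

#' Per-gene genotype comparisons of expression
#'
#' For each gene (and region): Mann-Whitney U on RQ between genotypes
#' (exact when the smaller group has <= 8 mice and no ties, normal
#' approximation with continuity/tie correction otherwise) and
#' Levene's test for homogeneity of variance (mean-centered by
#' default; `center = stats::median` gives Brown-Forsythe). P-values
#' are Benjamini-Hochberg adjusted across genes, separately for the
#' location and variance families, at each configured FDR level.
#'
#' @param rq_table Output of [compute_rq()] (or a table with an `rq`
#'   column).
#' @param config A [pipeline_config()].
#' @param center Centering function for Levene's test.
#' @return Data.frame per gene (x region): U, p_mw, levene_F, p_levene,
#'   BH-adjusted p's and decision columns at each FDR level.
#' @export
genotype_tests <- function(rq_table, config = pipeline_config(),
                           center = mean) {
  stopifnot(all(c("genotype", "gene", "rq") %in% names(rq_table)))
  gts <- sort(unique(as.character(rq_table$genotype)))
  if (length(gts) != 2) stop("exactly two genotypes required")
  keycols <- intersect(c("gene", "region"), names(rq_table))
  key <- interaction(rq_table[keycols], drop = TRUE, sep = "|")
  rows <- lapply(levels(key), function(k) {
    sub <- rq_table[key == k, , drop = FALSE]
    x <- sub$rq[sub$genotype == gts[1]]
    y <- sub$rq[sub$genotype == gts[2]]
    if (length(x) < 2 || length(y) < 2)
      stop("need >= 2 mice per genotype for ", k)
    use_exact <- min(length(x), length(y)) <= 8 &&
      !anyDuplicated(c(x, y))
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = use_exact,
                                              correct = TRUE))
    lev <- tryCatch({
      lt <- car::leveneTest(sub$rq, factor(sub$genotype), center = center)
      c(lt[1, "F value"], lt[1, "Pr(>F)"])
    }, error = function(e) c(NA_real_, NA_real_))
    df <- data.frame(gene = sub$gene[1], U = unname(wt$statistic),
                     p_mw = wt$p.value, levene_F = lev[1],
                     p_levene = lev[2])
    if ("region" %in% names(sub)) df$region <- sub$region[1]
    df
  })
  out <- do.call(rbind, rows)
  mw_adj <- bh_adjust(out$p_mw, fdr_levels = config$fdr_levels)
  lev_adj <- bh_adjust(out$p_levene, fdr_levels = config$fdr_levels)
  out$p_mw_bh <- mw_adj$p_adjusted
  out$p_levene_bh <- lev_adj$p_adjusted
  for (i in seq_along(config$fdr_levels)) {
    lv <- config$fdr_levels[i]
    out[[paste0("mw_fdr_", lv)]] <- mw_adj$decisions[, i]
    out[[paste0("levene_fdr_", lv)]] <- lev_adj$decisions[, i]
  }
  rownames(out) <- NULL
  out
}
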