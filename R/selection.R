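#' Assemble the feature matrix for predictor selection
#'
#' Joins, by mouse id, the P12 call features (type counts/proportions,
#' pair counts/proportions, Markov probabilities), the prefrontal-
#' cortex gene RQs, and the social-interaction response for one
#' genotype x session — one matrix per genotype x session, never
#' pooled across genotypes. Markov probabilities undefined for a mouse
#' (no outgoing connection from the first type) are imputed as 0:
#' an absent transition is zero evidence.
#'
#' @param call_features Output of [pup_features_table()] at P12.
#' @param rq_table Output of [compute_rq()].
#' @param scores Social score table (mouse_id, genotype, session,
#'   score_s).
#' @param genotype Genotype to model.
#' @param session Session (1 or 2).
#' @param region Expression region to use.
#' @return List of class `feature_matrix`: `X` (mice x features), `y`,
#'   `mouse_id`, `genotype`, `session`.
#' @export
build_feature_matrix <- function(call_features, rq_table, scores,
                                 genotype, session,
                                 region = "prefrontal_cortex") {
  sc <- scores[scores$genotype == genotype & scores$session == session, ]
  if (!nrow(sc)) stop("no scores for ", genotype, " session ", session)
  if (anyNA(sc$score_s)) stop("missing response values")
  rq <- rq_table
  if ("region" %in% names(rq)) rq <- rq[rq$region == region, ]
  rqw <- stats::reshape(rq[, c("mouse_id", "gene", "rq")],
                        idvar = "mouse_id", timevar = "gene",
                        direction = "wide")
  names(rqw) <- sub("^rq\\.", "", names(rqw))
  ids <- sc$mouse_id
  no_calls <- setdiff(ids, call_features$pup_id)
  no_expr <- setdiff(ids, rqw$mouse_id)
  if (length(no_calls) || length(no_expr))
    stop("mice without linked data - calls: ",
         paste(no_calls, collapse = ", "), "; expression: ",
         paste(no_expr, collapse = ", "))
  cf <- call_features[match(ids, call_features$pup_id), , drop = FALSE]
  Xc <- as.matrix(cf[, setdiff(names(cf), c("pup_id", "genotype")),
                     drop = FALSE])
  mp <- endsWith(colnames(Xc), "(MP)")
  Xc[, mp][is.na(Xc[, mp])] <- 0
  Xg <- as.matrix(rqw[match(ids, rqw$mouse_id),
                      setdiff(names(rqw), "mouse_id"), drop = FALSE])
  X <- cbind(Xc, Xg)
  rownames(X) <- ids
  if (anyNA(X))
    stop("NA features for mice: ",
         paste(ids[rowSums(is.na(X)) > 0], collapse = ", "))
  structure(list(X = X, y = sc$score_s, mouse_id = ids,
                 genotype = genotype, session = session),
            class = "feature_matrix")
}

# Standardize columns; drop constants, recording their names.
standardize_features <- function(X) {
  sdv <- apply(X, 2, stats::sd)
  keep <- !is.na(sdv) & sdv > 0
  Z <- scale(X[, keep, drop = FALSE])
  list(Z = Z, dropped = colnames(X)[!keep])
}

#' Lasso path with AIC model choice
#'
#' Fits the Gaussian Lasso over a log-spaced penalty path of 100
#' values from `lambda_max = max |X'y| / n` (the smallest penalty
#' zeroing every coefficient) down to `1e-3 * lambda_max`, on
#' standardized features. Along the path the Akaike Information
#' Criterion is `n * ln(RSS / n) + 2 * df`, with df the number of
#' nonzero coefficients (the standard unbiased df estimator for the
#' Lasso); the chosen penalty minimizes the criterion, ties going to
#' the larger (sparser) penalty.
#'
#' By default the small-sample correction
#' `AICc = AIC + 2 df (df + 1) / (n - df - 2)` is applied. With far
#' more candidate features than mice the uncorrected criterion is
#' degenerate: the residual sum of squares can be driven toward zero
#' at the dense end of the path, so `n * ln(RSS / n)` dominates and
#' the saturated fit always wins. The correction diverges as df
#' approaches n and restores a sparse optimum; `criterion = "aic"`
#' gives the uncorrected form.
#'
#' @param fm A `feature_matrix` from [build_feature_matrix()], or a
#'   list with elements `X` and `y`.
#' @param nlambda Path length.
#' @param lambda_min_ratio Smallest penalty as a fraction of
#'   `lambda_max`.
#' @param criterion `"aicc"` (default) or `"aic"`.
#' @return List of class `selection_result`: `lambda`, `df`, `r2`
#'   (fraction deviance explained), `aic` (the criterion values),
#'   `lambda_opt`, `selected` (named nonzero coefficients at the
#'   chosen penalty, standardized scale), `dropped` (constant
#'   features), `n`.
#' @export
lasso_aic <- function(fm, nlambda = 100, lambda_min_ratio = 1e-3,
                      criterion = c("aicc", "aic")) {
  criterion <- match.arg(criterion)
  X <- fm$X
  y <- fm$y
  n <- length(y)
  if (n < 10) stop("need n >= 10 mice")
  if (stats::sd(y) == 0) stop("response has zero variance")
  st <- standardize_features(X)
  Z <- st$Z
  yc <- y - mean(y)
  lambda_max <- max(abs(crossprod(Z, yc))) / n
  path <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                  length.out = nlambda))
  fit <- glmnet::glmnet(Z, y, family = "gaussian", alpha = 1,
                        lambda = path, standardize = FALSE,
                        intercept = TRUE, thresh = 1e-9)
  pred <- stats::predict(fit, newx = Z)
  rss <- colSums((y - pred)^2)
  df <- fit$df
  aic <- n * log(pmax(rss, 1e-12) / n) + 2 * df
  if (criterion == "aicc")
    aic <- aic + ifelse(n - df - 2 > 0, 2 * df * (df + 1) / (n - df - 2),
                        Inf)
  opt <- which.min(aic)            # path descends: first min = sparser
  beta <- fit$beta[, opt]
  structure(list(lambda = fit$lambda, df = df, r2 = fit$dev.ratio,
                 aic = aic, lambda_opt = fit$lambda[opt],
                 selected = beta[beta != 0], dropped = st$dropped,
                 n = n),
            class = "selection_result")
}

#' Subsample stability of the Lasso-AIC selection
#'
#' Repeats the selection after randomly excluding a handful of mice
#' (default 5, 6, 5, 6, 5 across five repeats; uniform without
#' replacement within a repeat, independent across repeats) and counts
#' how often each feature is selected. Features selected in at least
#' `stable_min` of the repeats are flagged stable.
#'
#' @param fm A `feature_matrix`.
#' @param n_repeats Number of repeats.
#' @param n_drop Mice dropped per repeat (recycled to `n_repeats`).
#' @param seed Integer seed.
#' @param stable_min Minimum count to flag a feature stable.
#' @param ... Passed to [lasso_aic()].
#' @return List: `counts` (named, all ever-selected features),
#'   `stable` (names), `sets` (per-repeat selected names).
#' @export
stability_selection <- function(fm, n_repeats = 5, n_drop = c(5, 6),
                                seed = 1L, stable_min = 3, ...) {
  n <- length(fm$y)
  n_drop <- rep(n_drop, length.out = n_repeats)
  if (any(n - n_drop < 10))
    stop("too few mice left after dropping (need >= 10)")
  set.seed(seed)
  sets <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    keep <- sort(sample(n, n - n_drop[r]))
    sub <- list(X = fm$X[keep, , drop = FALSE], y = fm$y[keep])
    sel <- lasso_aic(sub, ...)
    sets[[r]] <- names(sel$selected)
  }
  all_feats <- unique(unlist(sets))
  counts <- vapply(all_feats,
                   function(f) sum(vapply(sets, function(s) f %in% s, NA)),
                   0L)
  counts <- sort(counts, decreasing = TRUE)
  list(counts = counts, stable = names(counts)[counts >= stable_min],
       sets = sets)
}

#' Per-feature Pearson correlations with the response
#'
#' Validates selected predictors by plain correlation: Pearson r of
#' each requested feature against the response, ranked by |r|.
#' Zero-variance features get `NA`.
#'
#' @param fm A `feature_matrix`.
#' @param features Feature names to correlate; default all columns.
#' @return Data.frame: feature, r, abs_r, ordered by decreasing |r|.
#' @export
correlation_validation <- function(fm, features = colnames(fm$X)) {
  if (length(fm$y) < 3) stop("need n >= 3")
  missing_f <- setdiff(features, colnames(fm$X))
  if (length(missing_f))
    stop("unknown feature(s): ", paste(missing_f, collapse = ", "))
  r <- vapply(features, function(f) {
    x <- fm$X[, f]
    if (stats::sd(x) == 0) return(NA_real_)
    stats::cor(x, fm$y)
  }, 0)
  out <- data.frame(feature = features, r = r, abs_r = abs(r))
  out <- out[order(-out$abs_r, out$feature), ]
  rownames(out) <- NULL
  out
}
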