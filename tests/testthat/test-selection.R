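# Shared synthetic design: noise features plus named planted columns.
planted_design <- function(n, p_noise, planted, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * (p_noise + length(planted))), n)
  colnames(X) <- c(paste0("noise", seq_len(p_noise)), names(planted))
  y_sig <- as.numeric(X[, names(planted), drop = FALSE] %*% planted)
  list(X = X, y_sig = y_sig)
}

test_that("the feature matrix is assembled and linked correctly", {
  sc <- small_cohort()
  coh <- sc$cohort
  im <- fit_interval_model(coh$calls, sc$cfg)
  seg <- segment_calls(coh$calls, im)
  pf <- pup_features_table(seg[seg$genotype == "Dup", ], sc$cfg, age = 12)
  rq <- compute_rq(coh$expression, "WT")
  fm <- build_feature_matrix(pf, rq, coh$scores, "Dup", 2)
  expect_equal(ncol(fm$X), 533 + 11)
  expect_equal(nrow(fm$X), 25)
  expect_false(anyNA(fm$X))
  # spot-check three mice against independently assembled columns
  for (id in fm$mouse_id[c(1, 10, 25)]) {
    v <- pup_features(seg[seg$pup_id == id & seg$age_day == 12, ],
                      sc$cfg)
    expect_equal(unname(fm$X[id, "Har(N)"]), unname(v["Har(N)"]))
    expect_equal(unname(fm$X[id, "D_F(P)"]), unname(v["D_F(P)"]))
    expect_equal(unname(fm$X[id, "Magel2"]),
                 rq$rq[rq$mouse_id == id & rq$gene == "Magel2"])
  }
  # orphan mice are named in the error
  expect_error(build_feature_matrix(pf[-1, ], rq, coh$scores, "Dup", 2),
               pf$pup_id[1])
  rq_miss <- rq[rq$mouse_id != "DUP03", ]
  expect_error(build_feature_matrix(pf, rq_miss, coh$scores, "Dup", 2),
               "DUP03")
})

test_that("every coefficient is zero at the top of the penalty path", {
  d <- planted_design(30, 40, c(sig = 1.5), seed = 2)
  sel <- lasso_aic(list(X = d$X, y = d$y_sig + rnorm(30)))
  expect_equal(sel$df[1], 0)
  expect_gte(length(sel$lambda), 90)
  expect_true(all(diff(sel$lambda) < 0))
  # AIC-chosen model never fits worse than the empty model
  expect_lte(min(sel$aic), sel$aic[1])
})

test_that("a noise-free single-feature signal is recovered exactly", {
  d <- planted_design(25, 30, c(xj = 2), seed = 3)
  fm <- list(X = d$X, y = d$y_sig)           # response = 2 * xj exactly
  sel <- lasso_aic(fm)
  expect_equal(names(sel$selected), "xj")
  # smallest-penalty coefficient approaches 2 on the original scale
  st <- vocalpredict:::standardize_features(fm$X)
  fit <- glmnet::glmnet(st$Z, fm$y, lambda = min(sel$lambda),
                        standardize = FALSE)
  b <- fit$beta["xj", 1] / sd(fm$X[, "xj"])
  expect_equal(unname(b), 2, tolerance = 0.01)

  st5 <- stability_selection(fm, seed = 4)
  expect_equal(unname(st5$counts["xj"]), 5L)
  expect_equal(st5$stable, "xj")
})

test_that("selection is invariant to affine rescaling of a feature", {
  d <- planted_design(25, 20, c(a = 1.2, b = -1), seed = 5)
  y <- d$y_sig + rnorm(25, 0, 0.5)
  s1 <- lasso_aic(list(X = d$X, y = y))
  X2 <- d$X
  X2[, "a"] <- 1000 * X2[, "a"] + 77
  s2 <- lasso_aic(list(X = X2, y = y))
  expect_setequal(names(s1$selected), names(s2$selected))
})

test_that("a pure-noise response yields near-empty selections", {
  sizes <- integer(100)
  for (i in 1:100) {
    set.seed(i)
    X <- matrix(rnorm(29 * 20), 29)
    colnames(X) <- paste0("f", 1:20)
    sizes[i] <- length(lasso_aic(list(X = X, y = rnorm(29)))$selected)
  }
  expect_gte(mean(sizes <= 1), 0.60)
  expect_gte(mean(sizes <= 5), 0.85)
  expect_lte(median(sizes), 1)
})

test_that("planted signals at SNR 3 are recovered with few extras", {
  full <- logical(100)
  sizes <- integer(100)
  beta <- c(geneA = 1, geneB = 1, callF = 1)
  for (i in 1:100) {
    d <- planted_design(25, 30, beta, seed = i)
    y <- d$y_sig + rnorm(25, 0, 1)   # signal var 3 vs noise var 1
    sel <- names(lasso_aic(list(X = d$X, y = y))$selected)
    full[i] <- all(names(beta) %in% sel)
    sizes[i] <- length(sel)
  }
  expect_gte(mean(full), 0.80)
  expect_lte(median(sizes), 7)
})

test_that("stability counts stay low under the null", {
  nstab <- integer(30)
  for (i in 1:30) {
    set.seed(i)
    X <- matrix(rnorm(29 * 20), 29)
    colnames(X) <- paste0("f", 1:20)
    st <- stability_selection(list(X = X, y = rnorm(29)),
                              seed = i * 3 + 1)
    nstab[i] <- length(st$stable)
  }
  expect_lte(mean(nstab), 2)
  expect_gte(mean(nstab <= 2), 0.6)
})

test_that("correlation validation ranks and signs planted effects", {
  set.seed(6)
  X <- matrix(rnorm(25 * 10), 25)
  colnames(X) <- paste0("g", 1:10)
  y <- -X[, "g3"]
  cv <- correlation_validation(list(X = X, y = y))
  expect_equal(cv$feature[1], "g3")
  expect_equal(cv$r[1], -1)

  hits <- 0
  for (i in 1:100) {
    set.seed(i)
    if (abs(cor(rnorm(25), rnorm(25))) < 0.5) hits <- hits + 1
  }
  expect_gte(hits, 90)

  Xc <- cbind(X, const = 1)
  cvc <- correlation_validation(list(X = Xc, y = y))
  expect_true(is.na(cvc$r[cvc$feature == "const"]))
  expect_error(correlation_validation(list(X = X, y = y), "nope"),
               "unknown")
})

test_that("planted negative gene effects top the correlation ranking", {
  ok <- 0
  for (i in 1:100) {
    d <- planted_design(25, 10, c(gA = -1.3, gB = -1.3), seed = 200 + i)
    y <- d$y_sig + rnorm(25, 0, 1)
    cv <- correlation_validation(list(X = d$X, y = y))
    top2 <- cv$feature[1:2]
    if (setequal(top2, c("gA", "gB")) && all(cv$r[1:2] < 0)) ok <- ok + 1
  }
  expect_gte(ok, 80)
})
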