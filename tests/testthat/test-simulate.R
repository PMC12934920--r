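test_that("session generator honors degenerate regimes", {
  cfg <- pipeline_config(rng_seed = 1)
  prof <- genotype_profile("WT", cfg)
  prof$mean_call_count <- c(P8 = 0, P12 = 0)
  s <- simulate_pup_session(prof, 8, 42, cfg)
  expect_equal(nrow(s), 0)

  prof2 <- genotype_profile("WT", cfg)
  al <- cfg$alphabet
  prof2$pi <- setNames(as.numeric(al == "Har"), al)
  prof2$T <- diag(13)
  dimnames(prof2$T) <- list(al, al)
  prof2$mean_call_count <- c(P8 = 50, P12 = 50)
  s2 <- simulate_pup_session(prof2, 8, 42, cfg)
  expect_true(all(s2$call_type == "Har"))

  prof3 <- prof2
  prof3$T["Har", ] <- 0
  expect_error(simulate_pup_session(prof3, 8, 42, cfg), "degenerate")
})

test_that("generated transitions converge to the chain's matrix", {
  cfg <- pipeline_config(rng_seed = 4)
  al <- cfg$alphabet
  prof <- genotype_profile("WT", cfg)
  # uniform stationary mix so every row is visited ~ n/13 times
  prof$pi <- setNames(rep(1 / 13, 13), al)
  prof$T <- matrix(0.7 / 13, 13, 13, dimnames = list(al, al))
  diag(prof$T) <- diag(prof$T) + 0.3
  prof$mean_call_count <- c(P8 = 200000, P12 = 0)
  s <- simulate_pup_session(prof, 8, 99, cfg)
  s$pup_id <- "x"
  s$genotype <- "WT"
  seg <- segment_sequences(s, 1e9)
  tm <- transition_model(seg, cfg)
  expect_lt(max(abs(tm$P - prof$T)), 0.02)
})

test_that("generated gaps follow the stated exponential mixture", {
  cfg <- pipeline_config(rng_seed = 8)
  prof <- genotype_profile("WT", cfg)
  prof$mean_call_count <- c(P8 = 20000, P12 = 0)
  s <- simulate_pup_session(prof, 8, 7, cfg)
  gaps <- call_intervals(s[order(s$onset_s), ])
  # mixture mean: w/lambda_in + (1-w)/lambda_out = 0.9*80 + 0.1*2000
  expect_lt(abs(mean(gaps) - 272) / 272, 0.05)
  # short-gap mass: P(gap < 50) ~ w * (1 - exp(-50/80)) + small tail
  p50 <- 0.9 * (1 - exp(-50 / 80)) + 0.1 * (1 - exp(-50 / 2000))
  expect_lt(abs(mean(gaps < 50) - p50), 0.02)
})

test_that("noise-free expression hits the copy-number expectations", {
  panel <- data.frame(
    gene = c("NonImp", "Pat", "Mat"),
    imprinting = c("none", "paternal_expressed", "maternal_expressed"),
    inside_duplication = TRUE, amplification = 1,
    noise_sd_wt = 0, noise_sd_dup = 0)
  ct <- simulate_expression(panel, c(WT = 3, Dup = 3), seed = 1)
  rq <- compute_rq(ct, "WT")
  dup <- function(g) unique(rq$rq[rq$gene == g & rq$genotype == "Dup"])
  expect_equal(dup("NonImp"), 1.5)
  expect_equal(dup("Pat"), 2.0)
  expect_equal(dup("Mat"), 1.0)
  # amplification multiplies the noise-free RQ
  panel$amplification <- 1.5
  rq2 <- compute_rq(simulate_expression(panel, c(WT = 3, Dup = 3),
                                        seed = 1), "WT")
  expect_equal(unique(rq2$rq[rq2$gene == "NonImp" &
                               rq2$genotype == "Dup"]), 2.25)

  bad <- panel
  bad$imprinting[1] <- "both"
  expect_error(simulate_expression(bad, c(WT = 2, Dup = 2), seed = 1),
               "imprinting")
})

test_that("social scores follow the planted linear model", {
  feats <- data.frame(mouse_id = sprintf("m%02d", 1:25),
                      genotype = "Dup", x = rnorm(25, 2, 0.5))
  model <- list(intercepts = matrix(100, 2, 2,
                                    dimnames = list(c("WT", "Dup"),
                                                    c("session1", "session2"))),
                beta = c(x = 0), reference = c(x = 0), noise_sd = 0)
  sc <- simulate_social_scores(feats, model, seed = 1)
  expect_true(all(sc$score_s == 100))

  model$beta <- c(x = 3)
  sc2 <- simulate_social_scores(feats, model, seed = 1)
  s1 <- sc2[sc2$session == 1, ]
  expect_equal(s1$score_s, 100 + 3 * feats$x, tolerance = 1e-12)

  # with noise, OLS on the true feature recovers the coefficient
  model$noise_sd <- 4
  sc3 <- simulate_social_scores(feats, model, seed = 5)
  fit <- lm(sc3$score_s[sc3$session == 1] ~ feats$x)
  est <- coef(summary(fit))["feats$x", ]
  expect_lt(abs(est["Estimate"] - 3), 2 * est["Std. Error"])

  expect_error(simulate_social_scores(feats[, 1:2], model, seed = 1),
               "absent")
})

test_that("the default cohort has the study's shape and is reproducible", {
  sc <- small_cohort()
  coh <- sc$cohort
  expect_equal(length(unique(coh$calls$pup_id)), 54)
  sess <- unique(coh$calls[, c("pup_id", "age_day")])
  expect_equal(nrow(sess), 108)
  expect_equal(sum(coh$calls$genotype == "Dup" & coh$calls$age_day == 12) >
                 sum(coh$calls$genotype == "WT" & coh$calls$age_day == 12),
               TRUE)  # P12 call excess in Dup
  expect_equal(nrow(coh$expression), 54 * 11)
  expect_equal(nrow(coh$scores), 108)

  coh2 <- simulate_cohort(sc$cfg)
  expect_identical(coh$calls, coh2$calls)
  expect_identical(coh$expression, coh2$expression)
  expect_identical(coh$scores, coh2$scores)
})

test_that("a 4x expression-variance excess is detectable at study n", {
  panel <- data.frame(gene = "G", imprinting = "paternal_expressed",
                      inside_duplication = TRUE, amplification = 1,
                      noise_sd_wt = 0.15, noise_sd_dup = 0.30)
  hits <- 0
  for (i in 1:100) {
    ct <- simulate_expression(panel, c(WT = 29, Dup = 25), seed = i)
    rq <- compute_rq(ct, "WT")
    lt <- car::leveneTest(rq$rq, factor(rq$genotype), center = mean)
    if (lt[1, "Pr(>F)"] <= 0.05) hits <- hits + 1
  }
  expect_gte(hits, 80)
})
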