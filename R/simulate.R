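#' Default genotype profile for the call generator
#'
#' Encodes the generative structure the analysis assumes: per-age mean
#' call counts (Poisson), a first-order Markov chain over the 13 call
#' types (initial distribution `pi`, transition matrix `T`), a
#' two-component exponential mixture of inter-call gaps (within- vs
#' between-sequence rates, per ms) and the acoustic emission model
#' (four latent clusters shared across genotypes, each call type mapped
#' to one cluster). The duplication profile emits more calls at P12,
#' favors multi-component call types and spreads more transition mass
#' off the diagonal — more diverse call connections — while the
#' cluster geometry itself is genotype-independent.
#'
#' @param label `"WT"` or `"Dup"`.
#' @param config A [pipeline_config()].
#' @return A `genotype_profile` list.
#' @export
genotype_profile <- function(label = c("WT", "Dup"),
                             config = pipeline_config()) {
  label <- match.arg(label)
  al <- config$alphabet
  # stationary preferences; Dup shifts mass toward complex/multi-wave
  # types (Har, Su, Ts, Ms, Amb) and away from Sh, U, RCh
  pi_wt <- c(Har = 0.12, Su = 0.04, Ts = 0.02, Cx = 0.02, Sd = 0.04,
             Ms = 0.02, D = 0.16, Ch = 0.06, Sh = 0.20, F = 0.14,
             U = 0.12, RCh = 0.04, Amb = 0.02)
  pi_dup <- c(Har = 0.16, Su = 0.10, Ts = 0.07, Cx = 0.05, Sd = 0.07,
              Ms = 0.06, D = 0.12, Ch = 0.08, Sh = 0.08, F = 0.07,
              U = 0.05, RCh = 0.02, Amb = 0.07)
  pi <- (if (label == "WT") pi_wt else pi_dup)[al]
  self_w <- if (label == "WT") 0.45 else 0.30   # Dup: more off-diagonal
  T <- matrix(rep(pi, each = length(al)) * (1 - self_w),
              length(al), length(al), dimnames = list(al, al))
  diag(T) <- diag(T) + self_w
  T <- T / rowSums(T)
  structure(list(
    label = label,
    mean_call_count = if (label == "WT") c(P8 = 150, P12 = 150)
                      else c(P8 = 160, P12 = 260),
    lambda_in = 1 / 80,     # within-sequence gap rate, per ms
    lambda_out = 1 / 2000,  # between-sequence gap rate, per ms
    w = 0.9,                # mixture weight of the within component
    pi = pi, T = T,
    acoustic = acoustic_model()), class = "genotype_profile")
}

#' Default acoustic emission model
#'
#' Four latent clusters in the 7-feature space (bandwidth, max/mean/min
#' frequency, max/mean/min intensity); each call type emits from one
#' cluster with a small type-specific offset. Cluster centers are far
#' apart relative to the within-cluster spread, giving a well-separated
#' 4-component structure.
#'
#' @return List: `type_cluster` (named map type -> 1..4), per-cluster
#'   parameters.
#' @export
acoustic_model <- function() {
  list(
    type_cluster = c(Har = 1, Su = 1, Ts = 1, Ms = 1, Cx = 1,
                     Ch = 2, RCh = 2, Sd = 2,
                     Sh = 3, F = 3, U = 3, D = 3,
                     Amb = 4),
    freq_mean = c(95000, 72000, 52000, 38000),   # Hz
    freq_sd = c(1800, 1500, 1200, 1500),
    spread = c(11000, 7000, 2500, 5000),         # half-bandwidth scale
    spread_sd = c(1200, 900, 400, 700),
    int_mean = c(-42, -55, -48, -65),            # dB
    int_sd = c(1.2, 1.0, 0.8, 1.2),
    int_spread = c(6, 5, 3, 5),
    type_offset_hz = 800)
}

# Sample a first-order Markov chain of call types.
sample_markov <- function(n, pi, T, alphabet) {
  if (any(rowSums(T) == 0)) stop("degenerate transition matrix row")
  out <- character(n)
  if (n == 0) return(out)
  out[1] <- sample(alphabet, 1, prob = pi)
  for (i in seq_len(n - 1L))
    out[i + 1L] <- sample(alphabet, 1, prob = T[out[i], ])
  out
}

# Per-type call durations (ms): short calls short, others moderate.
sample_durations <- function(types) {
  base <- ifelse(types == "Sh", 6, ifelse(types %in% c("F", "U", "D"),
                                          35, 55))
  stats::rlnorm(length(types), log(base), 0.25)
}

# Acoustic feature draws for a vector of types.
sample_acoustics <- function(types, ac) {
  cl <- ac$type_cluster[types]
  n <- length(types)
  # deterministic per-type nudge keeps types distinguishable in-cluster
  off <- (match(types, names(ac$type_cluster)) - 7) * ac$type_offset_hz
  fmean <- stats::rnorm(n, ac$freq_mean[cl] + off, ac$freq_sd[cl])
  lo <- abs(stats::rnorm(n, ac$spread[cl], ac$spread_sd[cl]))
  hi <- abs(stats::rnorm(n, ac$spread[cl], ac$spread_sd[cl]))
  imean <- stats::rnorm(n, ac$int_mean[cl], ac$int_sd[cl])
  iup <- abs(stats::rnorm(n, ac$int_spread[cl], 1))
  idn <- abs(stats::rnorm(n, ac$int_spread[cl], 1))
  data.frame(bandwidth_hz = lo + hi,
             freq_max_hz = fmean + hi,
             freq_mean_hz = fmean,
             freq_min_hz = fmean - lo,
             intensity_max_db = imean + iup,
             intensity_mean_db = imean,
             intensity_min_db = imean - idn,
             cluster_true = as.integer(cl))
}

#' Simulate one pup recording session
#'
#' Call count ~ Poisson(mean for the age); call types follow the
#' profile's Markov chain; silent gaps between calls are drawn from the
#' two-component exponential mixture (clustered short gaps within
#' sequences, long gaps between); onsets accumulate gap + duration;
#' acoustic features come from the type's emission cluster.
#'
#' @param profile A [genotype_profile()].
#' @param age Age in days (must match a `mean_call_count` name as
#'   `P<age>`).
#' @param seed Integer seed.
#' @param config A [pipeline_config()].
#' @return Call-table rows for one session (no pup_id yet), plus
#'   ground-truth `cluster_true`.
#' @export
simulate_pup_session <- function(profile, age, seed,
                                 config = pipeline_config()) {
  set.seed(seed)
  mu <- profile$mean_call_count[paste0("P", age)]
  if (is.na(mu)) stop("profile has no mean call count for age ", age)
  n <- stats::rpois(1, mu)
  if (n == 0) {
    out <- sample_acoustics(character(0), profile$acoustic)
    out <- cbind(data.frame(age_day = integer(0), onset_s = numeric(0),
                            duration_ms = numeric(0)), out,
                 data.frame(harmonic_flag = logical(0),
                            call_type = character(0)))
    return(out)
  }
  types <- sample_markov(n, profile$pi, profile$T, config$alphabet)
  dur <- sample_durations(types)
  comp <- stats::runif(n) < profile$w
  gaps <- ifelse(comp, stats::rexp(n, profile$lambda_in),
                 stats::rexp(n, profile$lambda_out))   # ms
  onset <- numeric(n)
  onset[1] <- gaps[1] / 1000
  if (n > 1) for (i in 2:n)
    onset[i] <- onset[i - 1L] + dur[i - 1L] / 1000 + gaps[i] / 1000
  ac <- sample_acoustics(types, profile$acoustic)
  cbind(data.frame(age_day = age, onset_s = onset, duration_ms = dur),
        ac,
        data.frame(harmonic_flag = types == "Har", call_type = types))
}

#' Default qRT-PCR gene panel
#'
#' The murine orthologs of the duplicated interval plus the
#' outside-duplication control: non-imprinted duplicated genes (three
#' copies in Dup), paternally expressed imprinted genes (one active
#' copy in WT, two in Dup), the maternally expressed gene (paternal
#' copies silenced, so unchanged), and the outside-interval gene.
#' `amplification > 1` models over-proportional expression of the
#' Mkrn3 kind; Ct noise SDs are larger in Dup for the genes whose
#' expression the duplication makes more variable.
#'
#' @return Data.frame: gene, imprinting, inside_duplication,
#'   amplification, noise_sd_wt, noise_sd_dup.
#' @export
default_gene_panel <- function() {
  data.frame(
    gene = c("Herc2", "Gabrg3", "Gabra5", "Gabrb3", "Atp10a",
             "Snrpn", "Ndn", "Magel2", "Mkrn3", "Ube3a", "Cyfip1"),
    imprinting = c(rep("none", 5), rep("paternal_expressed", 4),
                   "maternal_expressed", "none"),
    inside_duplication = c(rep(TRUE, 10), FALSE),
    amplification = c(rep(1, 8), 1.5, 1, 1),
    noise_sd_wt = rep(0.15, 11),
    noise_sd_dup = c(0.50, 0.25, 0.25, 0.25, 0.25,
                     0.45, 0.45, 0.45, 0.55, 0.15, 0.15),
    stringsAsFactors = FALSE)
}

# Active expressed copies for one gene row under a genotype.
active_copies <- function(panel_row, genotype) {
  inside <- isTRUE(panel_row$inside_duplication)
  dup <- genotype == "Dup"
  switch(panel_row$imprinting,
         none = 2 + as.integer(dup && inside),
         paternal_expressed = 1 + as.integer(dup && inside),
         maternal_expressed = 1,
         stop("unknown imprinting status: ", panel_row$imprinting))
}

#' Simulate qRT-PCR Ct values under the copy-number model
#'
#' `Ct_target = Ct_housekeeping - log2(active_copies x amplification)
#' + N(0, noise SD)`, with active copies derived from copy counts and
#' imprinting status (paternal duplication: maternally expressed genes
#' keep one active copy) and the amplification factor applied in the
#' duplication genotype only. With zero noise the downstream
#' delta-delta-Ct RQ equals the active-copy ratio times the
#' amplification factor exactly.
#'
#' @param panel Gene panel as in [default_gene_panel()].
#' @param n_per_genotype Named counts, e.g. `c(WT = 29, Dup = 25)`.
#' @param seed Integer seed.
#' @param housekeeping_ct Housekeeping-gene Ct (cycles).
#' @param region Tissue label stored in the table.
#' @param mouse_ids Optional named list of ids per genotype.
#' @return Ct table: mouse_id, genotype, gene, region, ct_target,
#'   ct_housekeeping.
#' @export
simulate_expression <- function(panel = default_gene_panel(),
                                n_per_genotype = c(WT = 29, Dup = 25),
                                seed = 1L, housekeeping_ct = 20,
                                region = "prefrontal_cortex",
                                mouse_ids = NULL) {
  if (any(n_per_genotype < 1)) stop("need n >= 1 per genotype")
  if (any(panel$noise_sd_wt < 0 | panel$noise_sd_dup < 0))
    stop("noise SD must be >= 0")
  set.seed(seed)
  rows <- list()
  for (g in names(n_per_genotype)) {
    ids <- if (!is.null(mouse_ids)) mouse_ids[[g]]
           else sprintf("%s%02d", toupper(g), seq_len(n_per_genotype[[g]]))
    for (j in seq_len(nrow(panel))) {
      pr <- panel[j, ]
      level <- active_copies(pr, g) *
        (if (g == "Dup") pr$amplification else 1)
      sdv <- if (g == "Dup") pr$noise_sd_dup else pr$noise_sd_wt
      ct <- housekeeping_ct - log2(level) +
        stats::rnorm(length(ids), 0, sdv)
      rows[[length(rows) + 1L]] <- data.frame(
        mouse_id = ids, genotype = g, gene = pr$gene, region = region,
        ct_target = ct, ct_housekeeping = housekeeping_ct)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default behavior (social score) model
#'
#' Genotype x session intercepts in seconds of affiliative
#' interaction, a planted coefficient vector over named features
#' (gene expression in RQ units by default: higher Magel2 / Herc2
#' means less interaction), the reference feature values the
#' intercepts are anchored at (the WT expectation, so an intercept IS
#' the mean WT-reference score), and a Gaussian noise SD. Scores are
#' floored at 0. The planted coefficients give the gene-driven score
#' component a standard deviation of about three times the noise SD
#' in the duplication genotype — a strong, recoverable signal — while
#' the small WT expression variability leaves WT scores essentially
#' noise-driven.
#'
#' @return A `behavior_model` list: `intercepts` (matrix genotype x
#'   session), `beta` (named), `reference` (named), `noise_sd`.
#' @export
default_behavior_model <- function() {
  list(intercepts = matrix(c(170, 145, 165, 150), 2, 2, byrow = TRUE,
                           dimnames = list(c("WT", "Dup"),
                                           c("session1", "session2"))),
       beta = c(Magel2 = -40, Herc2 = -50),
       reference = c(Magel2 = 1, Herc2 = 1),
       noise_sd = 12)
}

#' Simulate social-interaction scores from a feature matrix
#'
#' `score = intercept(genotype, session) +
#' (features - reference) . beta + noise`, floored at 0; two sessions
#' per mouse with independent noise. With an all-zero reference this
#' is the plain linear model in the features.
#'
#' @param features Data.frame with `mouse_id`, `genotype` and the
#'   columns named by `model$beta`.
#' @param model A behavior model, see [default_behavior_model()].
#' @param seed Integer seed.
#' @return Data.frame: mouse_id, genotype, session, score_s.
#' @export
simulate_social_scores <- function(features,
                                   model = default_behavior_model(),
                                   seed = 1L) {
  missing_beta <- setdiff(names(model$beta), names(features))
  if (length(missing_beta))
    stop("beta names absent from features: ",
         paste(missing_beta, collapse = ", "))
  if (model$noise_sd < 0) stop("noise SD must be >= 0")
  set.seed(seed)
  X <- as.matrix(features[, names(model$beta), drop = FALSE])
  ref <- model$reference
  if (is.null(ref)) ref <- stats::setNames(numeric(ncol(X)), colnames(X))
  X <- sweep(X, 2, ref[colnames(X)])
  lin <- as.numeric(X %*% model$beta)
  rows <- list()
  for (s in 1:2) {
    ic <- model$intercepts[as.character(features$genotype),
                           paste0("session", s)]
    sc <- pmax(0, ic + lin + stats::rnorm(nrow(features), 0,
                                          model$noise_sd))
    rows[[s]] <- data.frame(mouse_id = features$mouse_id,
                            genotype = features$genotype,
                            session = s, score_s = sc)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a full linked cohort
#'
#' Generates, under one seed, the three linked tables the pipeline
#' consumes: per-call recordings for every mouse at both ages, the
#' qRT-PCR Ct table, and two-session social scores whose planted
#' dependence runs through the simulated gene expression levels. Mouse
#' ids are shared across modalities.
#'
#' @param config A [pipeline_config()]; `rng_seed` drives everything.
#' @param n_wt,n_dup Mice per genotype.
#' @param ages Recording ages (days).
#' @param profiles Named list of [genotype_profile()]s (`WT`, `Dup`).
#' @param panel Gene panel.
#' @param behavior Behavior model.
#' @return List: `calls` (validated call table), `expression` (Ct
#'   table), `scores`, `truth` (the generating parameters).
#' @export
simulate_cohort <- function(config = pipeline_config(),
                            n_wt = 29, n_dup = 25, ages = c(8, 12),
                            profiles = list(WT = genotype_profile("WT", config),
                                            Dup = genotype_profile("Dup", config)),
                            panel = default_gene_panel(),
                            behavior = default_behavior_model()) {
  seed <- config$rng_seed
  ids <- list(WT = sprintf("WT%02d", seq_len(n_wt)),
              Dup = sprintf("DUP%02d", seq_len(n_dup)))
  calls <- list()
  for (g in names(ids)) for (id in ids[[g]]) for (a in ages) {
    s <- simulate_pup_session(profiles[[g]], a,
                              child_seed(seed, paste0(id, "_P", a)),
                              config)
    if (nrow(s)) {
      s$pup_id <- id
      s$genotype <- g
      calls[[length(calls) + 1L]] <- s
    }
  }
  calls <- do.call(rbind, calls)
  calls <- validate_call_table(calls)
  expr <- simulate_expression(panel,
                              c(WT = n_wt, Dup = n_dup),
                              seed = child_seed(seed, "expression"),
                              mouse_ids = ids)
  # planted score dependence uses the true expression level 2^(-dCt)
  # in RQ units (normalized by the WT expectation), matching the scale
  # of the analysis-side RQ
  lev <- expr
  wt_level <- vapply(seq_len(nrow(panel)),
                     function(j) active_copies(panel[j, ], "WT"), 0)
  names(wt_level) <- panel$gene
  lev$level <- 2^(-(lev$ct_target - lev$ct_housekeeping)) /
    wt_level[lev$gene]
  wide <- stats::reshape(lev[, c("mouse_id", "genotype", "gene", "level")],
                         idvar = c("mouse_id", "genotype"),
                         timevar = "gene", direction = "wide")
  names(wide) <- sub("^level\\.", "", names(wide))
  wide <- wide[match(unlist(ids), wide$mouse_id), , drop = FALSE]
  scores <- simulate_social_scores(wide, behavior,
                                   seed = child_seed(seed, "scores"))
  list(calls = calls, expression = expr, scores = scores,
       truth = list(profiles = profiles, panel = panel,
                    behavior = behavior, seed = seed))
}
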