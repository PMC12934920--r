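# Build a minimal valid call-table session: acoustic columns are
# physically consistent placeholders unless overridden.
make_session <- function(onsets_s, durations_ms, types,
                         pup_id = "P1", age_day = 8, genotype = "WT") {
  n <- length(onsets_s)
  data.frame(pup_id = pup_id, age_day = age_day, genotype = genotype,
             onset_s = onsets_s,
             duration_ms = rep_len(durations_ms, n),
             bandwidth_hz = 10000, freq_max_hz = 65000,
             freq_mean_hz = 60000, freq_min_hz = 55000,
             intensity_max_db = -45, intensity_mean_db = -50,
             intensity_min_db = -55,
             harmonic_flag = types == "Har",
             call_type = types)
}

# Session with random types and gaps below/above a split threshold.
random_session <- function(n, seed, pup_id = "P1", age_day = 8,
                           genotype = "WT", gap_range = c(20, 900)) {
  set.seed(seed)
  types <- sample(call_type_alphabet(), n, replace = TRUE)
  dur <- runif(n, 10, 60)
  gaps <- runif(n, gap_range[1], gap_range[2])
  onsets <- cumsum(gaps / 1000 + c(0, dur[-n] / 1000))
  make_session(onsets, dur, types, pup_id, age_day, genotype)
}

# Small cohort shared by slower tests (generated once per run).
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- pipeline_config(rng_seed = 20240501)
      cache <<- list(cfg = cfg, cohort = simulate_cohort(cfg))
    }
    cache
  }
})
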