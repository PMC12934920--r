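#' The 13-type call alphabet
#'
#' Ordered labels for the 13 qualitative call types used throughout the
#' pipeline: harmonic (Har), step-up (Su), two-steps (Ts), complex (Cx),
#' step-down (Sd), multiple-steps (Ms), downward (D), chevron (Ch),
#' short (Sh), flat (F), upward (U), reverse chevron (RCh) and
#' ambiguous (Amb).
#'
#' @return Character vector of length 13.
#' @export
call_type_alphabet <- function() {
  c("Har", "Su", "Ts", "Cx", "Sd", "Ms", "D", "Ch", "Sh", "F", "U",
    "RCh", "Amb")
}

#' Pipeline configuration
#'
#' Holds every tunable of the pipeline in one validated object: the
#' recording length per pup session, the 13-type alphabet, the contour
#' classifier thresholds, the inter-call-interval crossing search
#' settings, the Markov tier multipliers and the FDR levels for
#' Benjamini-Hochberg decisions.
#'
#' @param session_duration Recording length per pup session, seconds.
#' @param alphabet Ordered character vector of the 13 call-type labels.
#' @param thresholds Named list of classifier thresholds: `jump_hz`
#'   (minimum frequency discontinuity counted as a pitch jump, Hz),
#'   `jump_ms` (maximum time span of a jump, ms), `short_ms` (calls
#'   shorter than this are "short", ms), `flat_hz` (total excursion below
#'   which a jump-free call is "flat", Hz), `chevron_hz` (minimum rise
#'   and fall of a chevron / reverse-chevron limb, Hz).
#' @param grid_step_ms Step of the sign-scan grid for the density
#'   crossing, ms.
#' @param bisect_tol_ms Bisection tolerance for the crossing, ms.
#' @param kde_bw Kernel bandwidth for the observed-interval density, ms;
#'   `NULL` uses Silverman's rule (`stats::bw.nrd0`).
#' @param tier_multipliers Chance multiples defining the transition
#'   display tiers (grey, light brown, dark brown).
#' @param fdr_levels False-discovery-rate levels, fractions in (0, 1).
#' @param rng_seed Integer seed from which all randomness flows.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(session_duration = 300,
                            alphabet = call_type_alphabet(),
                            thresholds = list(jump_hz = 10000,
                                              jump_ms = 10,
                                              short_ms = 10,
                                              flat_hz = 6000,
                                              chevron_hz = 6000),
                            grid_step_ms = 1,
                            bisect_tol_ms = 0.01,
                            kde_bw = NULL,
                            tier_multipliers = c(1.5, 2.0, 2.5),
                            fdr_levels = c(0.05, 0.10, 0.25),
                            rng_seed = 1L) {
  if (!is.numeric(session_duration) || session_duration <= 0)
    stop("session_duration must be > 0 seconds")
  if (length(alphabet) != 13 || anyDuplicated(alphabet))
    stop("alphabet must hold exactly 13 unique labels")
  needed <- c("jump_hz", "jump_ms", "short_ms", "flat_hz", "chevron_hz")
  missing_thr <- setdiff(needed, names(thresholds))
  if (length(missing_thr))
    stop("thresholds missing: ", paste(missing_thr, collapse = ", "))
  if (any(fdr_levels <= 0 | fdr_levels >= 1))
    stop("fdr_levels must lie in (0, 1)")
  structure(list(session_duration = session_duration,
                 alphabet = as.character(alphabet),
                 thresholds = thresholds,
                 grid_step_ms = grid_step_ms,
                 bisect_tol_ms = bisect_tol_ms,
                 kde_bw = kde_bw,
                 tier_multipliers = sort(tier_multipliers),
                 fdr_levels = sort(fdr_levels),
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

# Derive a reproducible child seed from a base seed and a stream label.
# Keeps results independent across streams while everything flows from
# one rng_seed; stays below 2^31.
child_seed <- function(seed, stream) {
  offs <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + offs) %% 2147483587)
}
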