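#' Required columns of a call table
#'
#' One row per detected call. `pup_id` + `age_day` key a recording
#' session; times are seconds from session start, durations
#' milliseconds, frequencies Hz, intensities dB.
#'
#' @return Character vector of required column names.
#' @export
call_table_columns <- function() {
  c("pup_id", "age_day", "onset_s", "duration_ms", "bandwidth_hz",
    "freq_max_hz", "freq_mean_hz", "freq_min_hz",
    "intensity_max_db", "intensity_mean_db", "intensity_min_db",
    "harmonic_flag")
}

#' Validate a call table
#'
#' Checks the schema and the physical invariants: required columns
#' present, positive durations, `freq_min <= freq_mean <= freq_max`,
#' and onsets non-decreasing within each (pup, age) session in row
#' order. Unknown extra columns (including `genotype`, `call_type`,
#' `contour`) are preserved untouched.
#'
#' @param df A data.frame of calls.
#' @return The validated data.frame, rows sorted by
#'   (pup_id, age_day, onset_s).
#' @export
validate_call_table <- function(df) {
  missing_cols <- setdiff(call_table_columns(), names(df))
  if (length(missing_cols))
    stop("call table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (any(df$duration_ms <= 0))
    stop("duration_ms must be > 0 (row ",
         which(df$duration_ms <= 0)[1], ")")
  bad_freq <- which(!(df$freq_min_hz <= df$freq_mean_hz &
                        df$freq_mean_hz <= df$freq_max_hz))
  if (length(bad_freq))
    stop("frequency ordering violated (freq_min <= freq_mean <= freq_max) ",
         "at row ", bad_freq[1])
  key <- interaction(df$pup_id, df$age_day, drop = TRUE)
  for (k in levels(key)) {
    idx <- which(key == k)
    ons <- df$onset_s[idx]
    if (is.unsorted(ons))
      stop("onset_s not non-decreasing within session ", k,
           " (row ", idx[which(diff(ons) < 0)[1] + 1L], ")")
  }
  df <- df[order(df$pup_id, df$age_day, df$onset_s), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a call table from CSV
#'
#' Reads the per-call output layer of a USV detection tool (one row per
#' call, VocalMat-style column conventions) and validates it.
#'
#' @param path Path to a CSV file (UTF-8, comma separated, `.` decimal).
#' @param config A [pipeline_config()] (reserved for dialect options).
#' @return A validated call table sorted by (pup_id, age_day, onset_s).
#' @export
read_call_table <- function(path, config = pipeline_config()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_call_table(df)
}

#' Write a bundle of result tables plus a manifest
#'
#' Writes one CSV per named element of `bundle` and a `manifest.json`
#' recording the file list, the seed and a hash of the configuration,
#' so a run is identifiable and exactly repeatable.
#'
#' @param bundle Named list of data.frames (may be empty).
#' @param out_dir Output directory; created if absent.
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest as a list.
#' @export
write_results <- function(bundle, out_dir, config = pipeline_config()) {
  if (length(bundle) && (is.null(names(bundle)) || any(names(bundle) == "")))
    stop("bundle elements must be named")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  files <- character(0)
  for (nm in names(bundle)) {
    f <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(bundle[[nm]], f, row.names = FALSE)
    files <- c(files, basename(f))
  }
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA, null = "null")
  tf <- tempfile()
  writeLines(as.character(cfg_json), tf)
  hash <- unname(tools::md5sum(tf))
  unlink(tf)
  manifest <- list(files = files, n_files = length(files),
                   seed = config$rng_seed, config_md5 = hash)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
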