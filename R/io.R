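# Plain-text interchange: stimulus sequences as CSV (one row per frame),
# event tables as TSV, results as long-format TSV and JSON.

#' Write / read stimulus luminance sequences (CSV)
#'
#' One row per frame with columns `sequence_id`, `frame_index`, `luminance`
#' (0-1 normalized).
#'
#' @param sequences Matrix sequences x frames.
#' @param path File path.
#' @export
write_sequences_csv <- function(sequences, path) {
  if (is.vector(sequences)) sequences <- matrix(sequences, nrow = 1)
  df <- data.frame(
    sequence_id = rep(seq_len(nrow(sequences)), each = ncol(sequences)),
    frame_index = rep(seq_len(ncol(sequences)), nrow(sequences)),
    luminance = as.vector(t(sequences)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sequences_csv
#' @return `read_sequences_csv` returns the sequences matrix.
#' @export
read_sequences_csv <- function(path) {
  df <- utils::read.csv(path)
  check(all(c("sequence_id", "frame_index", "luminance") %in% names(df)),
        "sequence CSV must have sequence_id, frame_index, luminance")
  ids <- sort(unique(df$sequence_id))
  nf <- max(df$frame_index)
  out <- matrix(NA_real_, length(ids), nf)
  for (i in seq_along(ids)) {
    d <- df[df$sequence_id == ids[i], ]
    out[i, d$frame_index] <- d$luminance
  }
  out
}

#' Write / read event tables (TSV)
#'
#' Columns: `sequence_id`, `frame_index`, `outcome` (`hit` / `miss`) and
#' `is_catch` flag.
#'
#' @param events Data frame with at least `sequence_id`, `frame_index`,
#'   `outcome` (0/1 or miss/hit); `is_catch` defaults to FALSE.
#' @param path File path.
#' @export
write_events_tsv <- function(events, path) {
  df <- events
  if (is.numeric(df$outcome)) {
    df$outcome <- ifelse(df$outcome == 1, "hit", "miss")
  }
  if (is.null(df$is_catch)) df$is_catch <- FALSE
  utils::write.table(df[, c("sequence_id", "frame_index", "outcome",
                            "is_catch")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @return `read_events_tsv` returns the events data frame with numeric
#'   `outcome` (1 = hit).
#' @export
read_events_tsv <- function(path) {
  df <- utils::read.delim(path)
  df$outcome <- as.integer(df$outcome == "hit" | df$outcome == "1")
  df
}

#' Export a POS result as long-format TSV
#'
#' @param result A `pos_result`.
#' @param path File path.
#' @param freqs,times Optional axes; when given, rows carry `freq` and
#'   `time` columns (cells in freq-major order).
#' @param alpha Level for the `sig` column (uncorrected).
#' @export
write_pos_tsv <- function(result, path, freqs = NULL, times = NULL,
                          alpha = 0.05) {
  stopifnot(inherits(result, "pos_result"))
  df <- data.frame(pos = result$pos, z = result$z, p = result$p,
                   sig = result$p < alpha)
  if (!is.null(freqs) && !is.null(times)) {
    df$freq <- rep(freqs, times = length(times))
    df$time <- rep(times, each = length(freqs))
    df <- df[, c("freq", "time", "pos", "z", "p", "sig")]
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a latency study to JSON
#'
#' The JSON carries a schema version, the resolved configuration (for
#' provenance) and one row per modulation frequency.
#'
#' @param study A `latency_study`.
#' @param path File path.
#' @export
write_study_json <- function(study, path) {
  stopifnot(inherits(study, "latency_study"))
  cfg <- study$config
  out <- list(
    schema_version = "1.0",
    config = list(mod_freqs = cfg$mod_freqs, n_datasets = cfg$n_datasets,
                  window_s = cfg$window, true_latency_s = cfg$true_latency,
                  alpha = cfg$alpha, wilcoxon_alpha = cfg$wilcoxon_alpha,
                  with_erp = cfg$with_erp, n_perm = cfg$n_perm,
                  n_time_points = cfg$n_time_points, seed = cfg$seed,
                  n_trials = cfg$noise_cfg$n_trials,
                  noise_sd = cfg$noise_cfg$sd,
                  noise_color = cfg$noise_cfg$color),
    rows = study$summary,
    times_s = study$times,
    percent_significant = study$percent_significant)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
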