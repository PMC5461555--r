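# Orchestration of the latency-distortion study: sweep phase-modulation
# frequencies, aggregate per-dataset significance time courses, median
# latencies with CIs, Wilcoxon tests against the true injection latency, and
# the latency-error vs window-duration correlation.

#' Default modulation-frequency grid
#'
#' 24 geometrically spaced frequencies from 3.99 to 100 Hz. The endpoints
#' match the printed sweep; individual study rows (e.g. 7.08 or 39.44 Hz)
#' can always be run at their exact frequency by passing `mod_freqs`
#' explicitly.
#'
#' @param n Number of frequencies.
#' @param fmin,fmax Range, Hz.
#' @return Numeric vector of frequencies.
#' @export
default_mod_freqs <- function(n = 24, fmin = 3.99, fmax = 100) {
  exp(seq(log(fmin), log(fmax), length.out = n))
}

#' Configuration of the latency-distortion study
#'
#' Defaults reproduce the study conditions: 100 datasets of 500 trials per
#' modulation frequency, cosine outcome modulation (70% at the preferred
#' phase) read out at +40 ms, P1/N1 evoked potentials added, wavelet cycles
#' following the 3-cycles-at-3-Hz to 8-cycles-at-100-Hz schedule, POS tested
#' per time point against 1000 label shuffles, Bonferroni correction across
#' the analysis window (-360 to +440 ms).
#'
#' @param mod_freqs Modulation frequencies, Hz.
#' @param n_datasets Datasets ("subjects") per frequency.
#' @param window Analysis window in seconds around target onset.
#' @param true_latency Injection latency, seconds.
#' @param alpha Bonferroni family-wise level.
#' @param wilcoxon_alpha Level for the signed-rank test of median latency
#'   against `true_latency`.
#' @param with_erp Add the evoked potential to each trial?
#' @param n_perm Label shuffles per dataset and time point.
#' @param n_time_points Optional decimation of the analysis window to this
#'   many equally spaced time points (e.g. 170 for literal replication of
#'   the printed analysis); `NULL` keeps the native sampling grid.
#' @param noise_cfg,erp,outcome Generator settings; see [noise_config()],
#'   [erp_params()], [outcome_model()].
#' @param plan Wavelet plan supplying the cycle schedule
#'   ([make_wavelet_plan()]).
#' @param seed Integer master seed; per-dataset seeds are derived
#'   deterministically from (seed, frequency index, dataset index).
#' @return Object of class `study_config`.
#' @export
study_config <- function(mod_freqs = default_mod_freqs(),
                         n_datasets = 100,
                         window = c(-0.360, 0.440),
                         true_latency = 0.040,
                         alpha = 0.05,
                         wilcoxon_alpha = 0.01,
                         with_erp = TRUE,
                         n_perm = 1000,
                         n_time_points = NULL,
                         noise_cfg = noise_config(),
                         erp = erp_params(),
                         outcome = outcome_model(),
                         plan = make_wavelet_plan(fs = noise_cfg$fs),
                         seed = 1) {
  check(window[1] < true_latency && true_latency < window[2],
        "analysis window must contain the true latency")
  check(n_datasets >= 1, "n_datasets must be >= 1")
  structure(list(mod_freqs = mod_freqs, n_datasets = as.integer(n_datasets),
                 window = window, true_latency = true_latency,
                 alpha = alpha, wilcoxon_alpha = wilcoxon_alpha,
                 with_erp = isTRUE(with_erp), n_perm = as.integer(n_perm),
                 n_time_points = n_time_points,
                 noise_cfg = noise_cfg, erp = erp, outcome = outcome,
                 plan = plan, seed = as.integer(seed)),
            class = "study_config")
}

# Sample indices of the analysis window on the dataset's time axis,
# optionally decimated to cfg$n_time_points points.
window_indices <- function(time, cfg) {
  i_lo <- which.min(abs(time - cfg$window[1]))
  i_hi <- which.min(abs(time - cfg$window[2]))
  if (is.null(cfg$n_time_points)) {
    i_lo:i_hi
  } else {
    unique(round(seq(i_lo, i_hi, length.out = cfg$n_time_points)))
  }
}

#' Analyse a single artificial dataset
#'
#' Generates one dataset at `mod_freq`, extracts wavelet phases at that
#' frequency (cycle count from the plan's schedule), tests POS against
#' label-shuffle surrogates at each analysis-window time point, applies the
#' Bonferroni threshold across the window, and returns the mean latency of
#' the largest significant cluster.
#'
#' @param mod_freq Modulation frequency, Hz.
#' @param cfg A [study_config()].
#' @param seed Seed for this dataset.
#' @return List: `latency` (s, `NA` if no significant point), `sig` mask,
#'   `times` (s), `z`, `p`, `n_sig`.
#' @export
run_dataset <- function(mod_freq, cfg, seed = cfg$seed) {
  ds <- build_simulated_dataset(mod_freq, noise_cfg = cfg$noise_cfg,
                                erp = cfg$erp, outcome = cfg$outcome,
                                with_erp = cfg$with_erp, seed = seed)
  idx <- window_indices(ds$time, cfg)
  pt <- wavelet_transform(ds$signals, cfg$plan, freqs = mod_freq,
                          time = ds$time)
  phases <- Arg(pt$coeffs[, 1, idx])
  res <- surrogate_pos(phases, ds$labels, n_perm = cfg$n_perm,
                       seed = derive_seed(seed, 7L))
  sig <- correct_multiple(res$p, "bonferroni", cfg$alpha)
  times <- ds$time[idx]
  list(latency = largest_cluster_latency(sig, times),
       sig = sig, times = times, z = res$z, p = res$p, n_sig = sum(sig))
}

#' Run the full latency-distortion study
#'
#' For each modulation frequency, analyses `n_datasets` independent
#' datasets, collects largest-cluster latencies (datasets with no
#' significant time point enter the percent-significant denominator but not
#' the latency distribution), and summarizes: median latency with its
#' quartile-based 95% CI, a Wilcoxon signed-rank test against the true
#' latency, the wavelet window duration, and the signed latency error
#' (true - median; positive = effect measured too early).
#'
#' @param cfg A [study_config()].
#' @param progress Print one line per frequency?
#' @return Object of class `latency_study`: `summary` data frame (one row
#'   per frequency), `latencies` (list of per-dataset latencies, s),
#'   `percent_significant` (frequency x time matrix, %), `times` (s),
#'   `config`.
#' @export
run_study <- function(cfg, progress = FALSE) {
  stopifnot(inherits(cfg, "study_config"))
  nf <- length(cfg$mod_freqs)
  lat <- vector("list", nf)
  pct <- NULL
  times <- NULL
  rows <- vector("list", nf)
  for (fi in seq_len(nf)) {
    f <- cfg$mod_freqs[fi]
    lats <- rep(NA_real_, cfg$n_datasets)
    sig_sum <- NULL
    for (di in seq_len(cfg$n_datasets)) {
      r <- run_dataset(f, cfg, seed = derive_seed(cfg$seed, fi, di))
      lats[di] <- r$latency
      if (is.null(sig_sum)) {
        sig_sum <- as.numeric(r$sig)
        times <- r$times
      } else {
        sig_sum <- sig_sum + r$sig
      }
    }
    if (is.null(pct)) pct <- matrix(0, nf, length(times))
    pct[fi, ] <- 100 * sig_sum / cfg$n_datasets
    lat[[fi]] <- lats
    n_def <- sum(is.finite(lats))
    if (n_def >= 2) {
      ld <- median_latency_ci(lats)
      wp <- suppressWarnings(stats::wilcox.test(
        lats[is.finite(lats)], mu = cfg$true_latency, exact = FALSE)$p.value)
      med <- ld$median
      ci <- c(ld$ci_low, ld$ci_high)
    } else {
      med <- NA_real_; ci <- c(NA_real_, NA_real_); wp <- NA_real_
    }
    rows[[fi]] <- data.frame(
      mod_freq = f,
      n_datasets = cfg$n_datasets,
      n_significant = n_def,
      median_latency_ms = 1000 * med,
      ci_low_ms = 1000 * ci[1],
      ci_high_ms = 1000 * ci[2],
      wilcoxon_p = wp,
      distorted = is.finite(wp) && wp < cfg$wilcoxon_alpha,
      window_duration_ms = 1000 * wavelet_window_duration(cfg$plan, f),
      latency_error_ms = 1000 * (cfg$true_latency - med))
    if (progress) {
      message(sprintf("%.2f Hz: median %.1f ms (%d/%d significant)",
                      f, 1000 * med, n_def, cfg$n_datasets))
    }
  }
  structure(list(summary = do.call(rbind, rows), latencies = lat,
                 percent_significant = pct, times = times, config = cfg),
            class = "latency_study")
}

#' Correlation between latency error and wavelet window duration
#'
#' Pearson correlation between the signed latency error (true latency minus
#' measured largest-cluster latency) and the wavelet window duration
#' cycles(f)/f at the modulation frequency. At `level = "dataset"` each
#' dataset contributes one (error, duration) pair; `level = "frequency"`
#' uses one pair per frequency (error of the median latency).
#'
#' @param study A `latency_study` from [run_study()].
#' @param level `"dataset"` or `"frequency"`.
#' @return Pearson correlation coefficient.
#' @export
latency_error_window_correlation <- function(study,
                                             level = c("dataset",
                                                       "frequency")) {
  stopifnot(inherits(study, "latency_study"))
  level <- match.arg(level)
  cfg <- study$config
  if (level == "frequency") {
    err <- study$summary$latency_error_ms
    dur <- study$summary$window_duration_ms
  } else {
    err <- unlist(lapply(seq_along(study$latencies), function(fi) {
      1000 * (cfg$true_latency - study$latencies[[fi]])
    }))
    dur <- unlist(lapply(seq_along(study$latencies), function(fi) {
      rep(study$summary$window_duration_ms[fi],
          length(study$latencies[[fi]]))
    }))
  }
  keep <- is.finite(err) & is.finite(dur)
  check(sum(keep) >= 3, "need at least 3 defined (error, duration) pairs")
  stats::cor(err[keep], dur[keep])
}
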