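# Synthetic-data generators for the latency-distortion study: background
# noise trials, a parameterized P1/N1 evoked potential, and cosine
# phase-dependent outcome assignment.

#' Configuration for background noise trials
#'
#' Defaults reproduce the study conditions: 500 trials of 3 s Gaussian white
#' noise (mean 0, SD 10 arbitrary units) sampled at 500 Hz, with the epoch
#' spanning -1.5 to +1.5 s around target onset. A pink (1/f power) option is
#' available for control simulations.
#'
#' @param n_trials Number of trials (>= 2).
#' @param n_samples Samples per trial.
#' @param fs Sampling rate in Hz.
#' @param mean,sd Mean and standard deviation of the noise, signal units.
#' @param color `"white"` or `"pink"` (power spectral density proportional
#'   to 1/f, DC removed; total variance rescaled to `sd^2`).
#' @param t_start Time of the first sample, seconds (target onset is 0).
#' @param seed Integer seed.
#' @return An object of class `noise_config`.
#' @export
noise_config <- function(n_trials = 500, n_samples = 1500, fs = 500,
                         mean = 0, sd = 10, color = c("white", "pink"),
                         t_start = -1.5, seed = 1) {
  color <- match.arg(color)
  check(n_trials >= 2, "n_trials must be >= 2")
  check(n_samples >= 1, "n_samples must be positive")
  check(fs > 0, "sampling rate must be positive")
  check(sd >= 0, "noise sd must be non-negative")
  structure(list(n_trials = as.integer(n_trials),
                 n_samples = as.integer(n_samples),
                 fs = fs, mean = mean, sd = sd, color = color,
                 t_start = t_start, seed = as.integer(seed)),
            class = "noise_config")
}

#' Generate background noise trials
#'
#' Draws a trials x samples matrix of Gaussian noise. In pink mode the white
#' draw is spectrally shaped with a 1/sqrt(f) amplitude filter (DC bin
#' zeroed) and rescaled so the expected variance equals `cfg$sd^2`.
#'
#' @param cfg A [noise_config()].
#' @return Numeric matrix `n_trials x n_samples` with attributes `fs` and
#'   `time` (sample times in seconds).
#' @export
generate_noise <- function(cfg) {
  stopifnot(inherits(cfg, "noise_config"))
  x <- with_seed(cfg$seed, matrix(
    stats::rnorm(cfg$n_trials * cfg$n_samples, 0, cfg$sd),
    nrow = cfg$n_trials))
  if (cfg$color == "pink" && cfg$sd > 0) {
    n <- cfg$n_samples
    f <- abs(fft_freqs(n, cfg$fs))
    amp <- ifelse(f > 0, 1 / sqrt(f), 0)
    amp <- amp / sqrt(mean(amp^2))      # preserve total variance
    x <- Re(ifft_rows(sweep(fft_rows(x), 2, amp, `*`)))
  }
  x <- x + cfg$mean
  attr(x, "fs") <- cfg$fs
  attr(x, "time") <- cfg$t_start + (seq_len(cfg$n_samples) - 1) / cfg$fs
  x
}

#' Parameters of the simulated evoked potential
#'
#' Two components: a positive P1 and a negative N1, each a raised-cosine
#' (Hann) bump whose amplitude, peak latency and duration are drawn per trial
#' from normal distributions. Defaults: P1 amplitude 20 (SD 5) units, peak
#' 65 ms (SD 10 ms), duration 50 ms (SD 10 ms); N1 amplitude 30 (SD 10)
#' units (applied negatively), peak 155 ms (SD 25 ms), duration 130 ms
#' (SD 25 ms). Amplitudes are in the same arbitrary units as the noise
#' (whose SD is 10).
#'
#' @param p1_amp_mean,p1_amp_sd,p1_lat_mean,p1_lat_sd,p1_dur_mean,p1_dur_sd
#'   P1 amplitude (units), peak latency (s) and duration (s), mean and SD.
#' @param n1_amp_mean,n1_amp_sd,n1_lat_mean,n1_lat_sd,n1_dur_mean,n1_dur_sd
#'   Same for the N1 (amplitude is the magnitude of the negative deflection).
#' @return An object of class `erp_params`.
#' @export
erp_params <- function(p1_amp_mean = 20, p1_amp_sd = 5,
                       p1_lat_mean = 0.065, p1_lat_sd = 0.010,
                       p1_dur_mean = 0.050, p1_dur_sd = 0.010,
                       n1_amp_mean = 30, n1_amp_sd = 10,
                       n1_lat_mean = 0.155, n1_lat_sd = 0.025,
                       n1_dur_mean = 0.130, n1_dur_sd = 0.025) {
  check(p1_dur_mean > 0 && n1_dur_mean > 0, "duration means must be positive")
  check(all(c(p1_amp_sd, p1_lat_sd, p1_dur_sd,
              n1_amp_sd, n1_lat_sd, n1_dur_sd) >= 0),
        "sd values must be non-negative")
  structure(as.list(environment()), class = "erp_params")
}

# Draw from N(mean, sd), redrawing values <= 0 (preserves the stated means
# better than clipping for the near-positive distributions used here).
draw_positive <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= 0]
  }
  x
}

# Raised-cosine bump of unit amplitude peaking at `lat` with total support
# `dur`, evaluated at times t.
hann_bump <- function(t, lat, dur) {
  u <- (t - lat) / dur
  ifelse(abs(u) < 0.5, 0.5 * (1 + cos(2 * pi * u)), 0)
}

#' Generate per-trial evoked potentials
#'
#' Each trial's waveform is the sum of a positive P1 bump and a negative N1
#' bump with parameters drawn independently per trial (see [erp_params()]).
#' Durations and latencies drawn non-positive are redrawn.
#'
#' @param params An [erp_params()] object.
#' @param n_trials Number of trials.
#' @param fs Sampling rate, Hz.
#' @param window Length-2 numeric, epoch window in seconds (must cover both
#'   component latencies).
#' @param seed Integer seed.
#' @return Matrix `n_trials x n_samples` with `fs` and `time` attributes.
#' @export
generate_erp_trials <- function(params, n_trials, fs, window = c(-1.5, 1.5),
                                seed = 1) {
  stopifnot(inherits(params, "erp_params"))
  check(window[1] < params$p1_lat_mean && window[2] > params$n1_lat_mean,
        "epoch window must cover both component latencies")
  n_samples <- round((window[2] - window[1]) * fs) + 1L
  t <- window[1] + (seq_len(n_samples) - 1) / fs
  with_seed(seed, {
    p1_amp <- stats::rnorm(n_trials, params$p1_amp_mean, params$p1_amp_sd)
    p1_lat <- draw_positive(n_trials, params$p1_lat_mean, params$p1_lat_sd)
    p1_dur <- draw_positive(n_trials, params$p1_dur_mean, params$p1_dur_sd)
    n1_amp <- stats::rnorm(n_trials, params$n1_amp_mean, params$n1_amp_sd)
    n1_lat <- draw_positive(n_trials, params$n1_lat_mean, params$n1_lat_sd)
    n1_dur <- draw_positive(n_trials, params$n1_dur_mean, params$n1_dur_sd)
    x <- matrix(0, n_trials, length(t))
    for (k in seq_len(n_trials)) {
      x[k, ] <- p1_amp[k] * hann_bump(t, p1_lat[k], p1_dur[k]) -
                n1_amp[k] * hann_bump(t, n1_lat[k], n1_dur[k])
    }
    attr(x, "fs") <- fs
    attr(x, "time") <- t
    x
  })
}

#' Cosine phase-dependence model for trial outcomes
#'
#' Describes how the probability of outcome A depends on the oscillatory
#' phase at the injection point. Under the default multiplicative convention
#' `P(A | angle) = p_mean * (1 + mod * cos(angle))`, the study defaults
#' (`p_mean = 0.5`, `mod = 0.4`) give a 70% chance of outcome A at phase 0
#' and 70% of outcome B at phase pi. The additive convention
#' `P(A | angle) = p_mean + mod * cos(angle)` is also available.
#'
#' @param p_mean Overall probability of outcome A.
#' @param mod Modulation depth (dimensionless).
#' @param phase_freq Frequency (Hz) at which the phase is read out.
#' @param phase_time Read-out time in seconds relative to target onset.
#' @param convention `"multiplicative"` (default) or `"additive"`.
#' @return An object of class `outcome_model`.
#' @export
outcome_model <- function(p_mean = 0.5, mod = 0.4, phase_freq = NA_real_,
                          phase_time = 0.040,
                          convention = c("multiplicative", "additive")) {
  convention <- match.arg(convention)
  check(p_mean >= 0 && p_mean <= 1, "p_mean must be a probability")
  pk <- outcome_probability(0, p_mean, mod, convention)
  pt <- outcome_probability(pi, p_mean, mod, convention)
  check(pk <= 1 && pk >= 0 && pt <= 1 && pt >= 0,
        "model yields probabilities outside [0, 1]")
  structure(list(p_mean = p_mean, mod = mod, phase_freq = phase_freq,
                 phase_time = phase_time, convention = convention),
            class = "outcome_model")
}

outcome_probability <- function(angle, p_mean, mod, convention) {
  if (convention == "multiplicative") p_mean * (1 + mod * cos(angle))
  else p_mean + mod * cos(angle)
}

#' Assign binary outcomes from phases
#'
#' Bernoulli draw per trial with success probability given by the cosine
#' rule of the [outcome_model()].
#'
#' @param phases Numeric vector of phase angles (radians), one per trial.
#' @param model An [outcome_model()].
#' @param seed Integer seed.
#' @return Integer vector of outcomes, 1 = A (or hit), 0 = B (or miss).
#' @export
assign_outcomes <- function(phases, model, seed = 1) {
  stopifnot(inherits(model, "outcome_model"))
  check(all(is.finite(phases)), "phases must be finite")
  p <- outcome_probability(phases, model$p_mean, model$mod, model$convention)
  check(all(p >= 0 & p <= 1), "model yields probabilities outside [0, 1]")
  with_seed(seed, as.integer(stats::rbinom(length(p), 1L, p)))
}

#' Build one artificial dataset for the latency study
#'
#' Pipeline: (1) generate background noise trials; (2) extract the phase at
#' `outcome$phase_time` (default +40 ms) from the `mod_freq` +/- 1 Hz band
#' via the analytic signal; (3) assign outcome labels by the cosine rule;
#' (4) optionally add per-trial P1/N1 evoked potentials, drawn from the same
#' process for both outcome groups and added after labelling.
#'
#' @param mod_freq Frequency (Hz) at which the phase modulation is injected;
#'   must exceed the 1 Hz band half-width and be below Nyquist.
#' @param noise_cfg A [noise_config()] (its `seed` is overridden by `seed`).
#' @param erp An [erp_params()].
#' @param outcome An [outcome_model()].
#' @param with_erp Add the evoked potential?
#' @param halfwidth Band half-width for phase extraction, Hz.
#' @param seed Integer seed; deterministic sub-seeds are derived for the
#'   noise, labelling and evoked-potential steps.
#' @return A list of class `simulated_dataset` with elements `signals`
#'   (trials x samples), `time`, `fs`, `labels`, `truth` (the outcome model
#'   with `phase_freq` filled in) and `with_erp`.
#' @export
build_simulated_dataset <- function(mod_freq,
                                    noise_cfg = noise_config(),
                                    erp = erp_params(),
                                    outcome = outcome_model(),
                                    with_erp = TRUE,
                                    halfwidth = 1,
                                    seed = 1) {
  check(mod_freq - halfwidth > 0, "mod_freq - halfwidth must be positive")
  check(mod_freq + halfwidth < noise_cfg$fs / 2,
        "modulation band must lie below Nyquist")
  noise_cfg$seed <- derive_seed(seed, 1L)
  x <- generate_noise(noise_cfg)
  t <- attr(x, "time")
  idx <- which.min(abs(t - outcome$phase_time))
  ph <- band_phase_at(x, noise_cfg$fs, mod_freq, halfwidth, idx)
  labels <- assign_outcomes(ph, outcome, seed = derive_seed(seed, 2L))
  if (with_erp) {
    e <- generate_erp_trials(erp, noise_cfg$n_trials, noise_cfg$fs,
                             window = range(t), seed = derive_seed(seed, 3L))
    x <- x + e
  }
  truth <- outcome
  truth$phase_freq <- mod_freq
  structure(list(signals = x, time = t, fs = noise_cfg$fs, labels = labels,
                 truth = truth, with_erp = with_erp),
            class = "simulated_dataset")
}
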