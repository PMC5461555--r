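# Synthetic observer for the white-noise paradigm: random luminance
# sequences with embedded mean-gray targets, EEG recorded as a linear
# impulse response driven by the stimulus plus noise, and detection
# probability governed by the phase of the stimulus-driven signal at a known
# frequency and latency.

#' Synthetic impulse response function
#'
#' A synthetic per-channel kernel built from damped sinusoids (6 and 10 Hz
#' components under exponential decay over 0-500 ms), loosely shaped like a
#' visual impulse response with a perceptual-echo-like tail. Channel gains
#' taper away from `peak_channel` so topography recovery is testable.
#'
#' @param n_channels Number of channels.
#' @param fs Sampling rate (Hz; the stimulus frame rate).
#' @param duration Kernel support, seconds.
#' @param peak_channel Channel with the strongest response.
#' @return Object of class `irf`: `kernel` (channels x lags), `lags`
#'   (seconds), `fs`.
#' @export
synthetic_irf <- function(n_channels = 4, fs = 160, duration = 0.5,
                          peak_channel = 1) {
  lags <- seq(0, duration, by = 1 / fs)
  base <- exp(-lags / 0.12) * sin(2 * pi * 10 * lags) +
    0.8 * exp(-lags / 0.20) * sin(2 * pi * 6 * lags)
  gain <- 1 / (1 + abs(seq_len(n_channels) - peak_channel))
  irf(kernel = outer(gain, base), lags = lags, fs = fs)
}

#' Construct an impulse response object
#' @param kernel Numeric matrix channels x lags (signal units per luminance
#'   unit); a vector is treated as one channel.
#' @param lags Lag axis, seconds (starting at >= 0).
#' @param fs Sampling rate, Hz.
#' @return Object of class `irf`.
#' @export
irf <- function(kernel, lags, fs) {
  if (is.vector(kernel)) kernel <- matrix(kernel, nrow = 1)
  check(all(is.finite(kernel)), "kernel must be finite")
  check(lags[1] >= 0, "lag axis must start at or after 0")
  check(ncol(kernel) == length(lags), "kernel and lag axis must align")
  structure(list(kernel = kernel, lags = lags, fs = fs), class = "irf")
}

#' Configuration of the synthetic observer
#'
#' Defaults mirror the experimental protocol: 6.25 s sequences at a 160 Hz
#' frame rate (1000 frames), two to four embedded targets per sequence whose
#' frames carry exactly the mean-gray luminance, with 14 frames before and
#' 11 frames after each target forced to mean gray. Detection probability is
#' `det_base * (1 + det_mod * cos(phi - phi0))` where `phi` is the phase of
#' the stimulus-driven (reconstructed) signal on `det_channel` at
#' `det_freq`, `det_latency` after target onset.
#'
#' @param irf_true An [irf()]; the generator's ground-truth kernel.
#' @param seq_duration Sequence duration, seconds.
#' @param frame_rate Frames per second.
#' @param n_sequences Number of sequences.
#' @param targets_range Integer range (min, max) of targets per sequence.
#' @param suppress_before,suppress_after Frames forced to mean gray around
#'   each target.
#' @param noise_sd SD of additive Gaussian sensor noise, signal units.
#' @param det_base Baseline hit probability.
#' @param det_mod Modulation depth of detection by phase.
#' @param det_freq Frequency of the phase read-out, Hz.
#' @param det_latency Read-out latency after target onset, seconds.
#' @param det_phase0 Preferred phase (radians).
#' @param det_channel Channel whose phase drives detection.
#' @param mean_gray Mean luminance (0-1 scale).
#' @param seed Integer seed.
#' @return Object of class `observer_config`.
#' @export
observer_config <- function(irf_true = synthetic_irf(),
                            seq_duration = 6.25,
                            frame_rate = 160,
                            n_sequences = 48,
                            targets_range = c(2, 4),
                            suppress_before = 14,
                            suppress_after = 11,
                            noise_sd = 1,
                            det_base = 0.5,
                            det_mod = 0.4,
                            det_freq = 6,
                            det_latency = 0.075,
                            det_phase0 = 0,
                            det_channel = 1,
                            mean_gray = 0.5,
                            seed = 1) {
  check(suppress_before >= 0 && suppress_after >= 0,
        "suppression windows must be non-negative")
  check(det_base * (1 + det_mod) <= 1 && det_base * (1 - det_mod) >= 0,
        "detection probabilities must stay in [0, 1]")
  check(frame_rate > 0 && seq_duration > 0, "invalid sequence geometry")
  stopifnot(inherits(irf_true, "irf"))
  structure(as.list(environment()), class = "observer_config")
}

# Causal convolution of a kernel with a sequence, output length = input
# length; lag 0 of the kernel multiplies the current frame.
conv_causal <- function(kernel, x) {
  n <- length(x)
  L <- length(kernel)
  npad <- stats::nextn(n + L, 2)
  y <- Re(stats::fft(stats::fft(c(kernel, rep(0, npad - L))) *
                     stats::fft(c(x, rep(0, npad - n))), inverse = TRUE)) /
    npad
  y[seq_len(n)]
}

# Place k targets in a sequence of n frames such that suppression windows
# and epoching margins never overlap; rejection sampling with a fallback to
# fewer targets is not needed at the default geometry.
place_targets <- function(n_frames, k, before, after, margin) {
  guard <- before + after + 1L
  for (attempt in 1:200) {
    pos <- sort(sample((margin + before + 1L):(n_frames - margin - after),
                       k))
    if (k == 1L || all(diff(pos) > guard)) return(pos)
  }
  stop_invalid("could not place %d targets with the requested spacing", k)
}

#' Generate a synthetic observer dataset
#'
#' Draws random luminance sequences (uniform on (0, 1)), embeds mean-gray
#' targets with mean-gray suppression windows, simulates the recorded EEG as
#' the true impulse response convolved with the mean-centred stimulus plus
#' Gaussian noise, and draws hit/miss outcomes from the phase of the
#' noise-free stimulus-driven signal at the configured frequency and
#' latency.
#'
#' @param cfg An [observer_config()].
#' @param sequences Optional pre-built luminance matrix (sequences x
#'   frames), e.g. to present identical sequences to several synthetic
#'   subjects; targets/suppression must already be embedded and `events`
#'   supplied.
#' @param events Optional events data frame matching `sequences`.
#' @return Object of class `observer_dataset`: `sequences` (matrix), `events`
#'   (data frame: sequence_id, frame_index, time, outcome), `recorded`
#'   (array sequences x channels x frames), `irf_true`, `config`.
#' @export
generate_observer <- function(cfg, sequences = NULL, events = NULL) {
  stopifnot(inherits(cfg, "observer_config"))
  n_frames <- round(cfg$seq_duration * cfg$frame_rate)
  fs <- cfg$frame_rate
  n_ch <- nrow(cfg$irf_true$kernel)
  if (is.null(sequences)) {
    built <- with_seed(derive_seed(cfg$seed, 1L), {
      seqs <- matrix(stats::runif(cfg$n_sequences * n_frames),
                     cfg$n_sequences, n_frames)
      ev <- list()
      margin <- ceiling(0.8 * fs)  # keep epochs inside the sequence
      for (s in seq_len(cfg$n_sequences)) {
        k <- sample(cfg$targets_range[1]:cfg$targets_range[2], 1)
        pos <- place_targets(n_frames, k, cfg$suppress_before,
                             cfg$suppress_after, margin)
        for (p in pos) {
          win <- (p - cfg$suppress_before):(p + cfg$suppress_after)
          seqs[s, win] <- cfg$mean_gray
        }
        ev[[s]] <- data.frame(sequence_id = s, frame_index = pos,
                              time = (pos - 1) / fs)
      }
      list(seqs = seqs, events = do.call(rbind, ev))
    })
    sequences <- built$seqs
    events <- built$events
  } else {
    check(!is.null(events), "events must accompany pre-built sequences")
    check(ncol(sequences) == n_frames, "sequence length mismatch")
  }
  # stimulus-driven signal (noise free), used both for the recording and
  # for the generative detection rule
  driven <- array(0, c(nrow(sequences), n_ch, n_frames))
  for (s in seq_len(nrow(sequences))) {
    xc <- sequences[s, ] - mean(sequences[s, ])
    for (ch in seq_len(n_ch)) {
      driven[s, ch, ] <- conv_causal(cfg$irf_true$kernel[ch, ], xc)
    }
  }
  recorded <- driven
  if (cfg$noise_sd > 0) {
    recorded <- recorded + with_seed(
      derive_seed(cfg$seed, 2L),
      array(stats::rnorm(length(driven), 0, cfg$noise_sd), dim(driven)))
  }
  # detection: phase of the driven signal at (det_freq, target + latency)
  plan <- make_wavelet_plan(fmin = 3, fmax = min(100, fs / 2 - 1),
                            n_freqs = 50, cmin = 2, cmax = 8, fs = fs)
  phi <- numeric(nrow(events))
  for (s in unique(events$sequence_id)) {
    rows <- which(events$sequence_id == s)
    pt <- wavelet_transform(matrix(driven[s, cfg$det_channel, ], 1),
                            plan, freqs = cfg$det_freq)
    at <- events$frame_index[rows] + round(cfg$det_latency * fs)
    phi[rows] <- Arg(pt$coeffs[1, 1, at])
  }
  p_hit <- cfg$det_base * (1 + cfg$det_mod * cos(phi - cfg$det_phase0))
  events$outcome <- with_seed(derive_seed(cfg$seed, 3L),
                              as.integer(stats::rbinom(length(p_hit), 1L,
                                                       p_hit)))
  events$phase_true <- phi
  structure(list(sequences = sequences, events = events,
                 recorded = recorded, irf_true = cfg$irf_true,
                 config = cfg, fs = fs),
            class = "observer_dataset")
}
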