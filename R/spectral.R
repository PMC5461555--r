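# Time-frequency machinery: narrow-band analytic-signal phase and a complex
# Morlet wavelet transform with log-spaced frequencies and log-interpolated
# cycle counts.

# Frequency response (real, zero-phase) of a forward-backward Hamming-
# windowed FIR bandpass, times the analytic-signal gain, over the DFT bins
# of an n-sample signal at rate fs. The FIR order is tied to the lower band
# edge (order ~ 3 fs / (f0 - hw), rounded to even), the convention of
# standard EEG filtering routines: a fixed narrow absolute bandwidth at a
# high centre frequency would need an impractically long filter, so the
# effective transition width grows in proportion to the band's lower edge.
# Forward-backward application squares the magnitude response, giving zero
# phase; negative frequencies are zeroed with gain 2 on positive
# frequencies so the real part of the output reproduces the band-passed
# input.
band_analytic_gain <- function(n, fs, f0, hw) {
  f_lo <- f0 - hw
  f_hi <- f0 + hw
  ord <- max(4L, 2L * as.integer(floor(3 * fs / f_lo / 2)))
  m <- ord / 2
  k <- seq.int(-m, m)
  h <- ifelse(k == 0, 2 * (f_hi - f_lo) / fs,
              (sin(2 * pi * f_hi * k / fs) -
                 sin(2 * pi * f_lo * k / fs)) / (pi * k))
  w <- 0.54 - 0.46 * cos(2 * pi * (k + m) / ord)
  b <- h * w
  b <- b / sum(b * cos(2 * pi * f0 * k / fs))  # unit gain at f0
  f <- fft_freqs(n, fs)
  # symmetric kernel => real response H(f) = sum_k b_k cos(2 pi f k / fs)
  H <- as.vector(cos(2 * pi * outer(f, k) / fs) %*% b)
  g <- 2 * H^2
  g[f <= 0] <- 0
  g
}

#' Narrow-band instantaneous phase via the analytic signal
#'
#' Band-passes each trial around `f0` (nominal passband `f0 +/- halfwidth`)
#' and simultaneously forms the analytic signal; returns its instantaneous
#' phase. The filter emulates a forward-backward Hamming-windowed FIR whose
#' order is tied to the lower band edge (order ~ `3 fs / (f0 - halfwidth)`),
#' applied as its squared magnitude response in the frequency domain, so the
#' effective transition width scales with the band's lower edge. Zero phase
#' is essential here: any filter delay would bias the very latencies this
#' package studies.
#'
#' @param x Numeric matrix, trials x samples (a vector is treated as one
#'   trial).
#' @param fs Sampling rate, Hz.
#' @param f0 Band centre frequency, Hz.
#' @param halfwidth Band half-width, Hz (default 1).
#' @return Matrix of phases in (-pi, pi], trials x samples.
#' @export
hilbert_band_phase <- function(x, fs, f0, halfwidth = 1) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  check(f0 - halfwidth > 0, "band must lie above 0 Hz")
  check(f0 + halfwidth < fs / 2, "band must lie below Nyquist")
  g <- band_analytic_gain(ncol(x), fs, f0, halfwidth)
  a <- ifft_rows(sweep(fft_rows(x), 2, g, `*`))
  Arg(a)
}

# Fast path: complex analytic value at selected sample indices only.
# Identical to hilbert_band_phase up to evaluating the inverse DFT at `idx`.
band_phase_at <- function(x, fs, f0, halfwidth, idx) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  g <- band_analytic_gain(n, fs, f0, halfwidth)
  bins <- which(g > 0)
  S <- fft_rows(x)[, bins, drop = FALSE]
  S <- sweep(S, 2, g[bins], `*`)
  # inverse DFT at sample idx (0-based exponent)
  ph <- sapply(idx, function(i) {
    w <- exp(2i * pi * (bins - 1) * (i - 1) / n)
    Arg(S %*% w)
  })
  if (length(idx) == 1L) as.numeric(ph) else ph
}

#' Build a wavelet analysis plan
#'
#' Frequencies are geometrically spaced between `fmin` and `fmax`; the
#' number of cycles varies geometrically from `cmin` at `fmin` to `cmax`
#' at `fmax`. The effective window duration at frequency f is cycles(f)/f,
#' e.g. 1 s at 3 Hz (3 cycles) down to 80 ms at 100 Hz (8 cycles) under the
#' default schedule.
#'
#' @param fmin,fmax Frequency range, Hz.
#' @param n_freqs Number of frequency steps (>= 2).
#' @param cmin,cmax Cycle counts at `fmin` and `fmax`.
#' @param fs Sampling rate of the signals to be analysed, Hz.
#' @return An object of class `wavelet_plan` with elements `freqs`,
#'   `cycles`, `fs` and the schedule parameters.
#' @export
make_wavelet_plan <- function(fmin = 3, fmax = 100, n_freqs = 50,
                              cmin = 3, cmax = 8, fs = 500) {
  check(fmin < fmax, "fmin must be below fmax")
  check(cmin <= cmax, "cmin must not exceed cmax")
  check(n_freqs >= 2, "n_freqs must be >= 2")
  check(cmin >= 1, "minimum cycle count is 1")
  check(fmax < fs / 2, "fmax must be below Nyquist")
  freqs <- exp(seq(log(fmin), log(fmax), length.out = n_freqs))
  structure(list(freqs = freqs,
                 cycles = cycles_at(freqs, fmin, fmax, cmin, cmax),
                 fs = fs, fmin = fmin, fmax = fmax,
                 cmin = cmin, cmax = cmax),
            class = "wavelet_plan")
}

cycles_at <- function(f, fmin, fmax, cmin, cmax) {
  if (cmin == cmax) return(rep(cmin, length(f)))
  cmin * (f / fmin)^(log(cmax / cmin) / log(fmax / fmin))
}

#' Cycle count of a plan at arbitrary frequencies
#' @param plan A [make_wavelet_plan()] object.
#' @param f Frequencies, Hz.
#' @return Cycle counts (geometric interpolation of the plan's schedule).
#' @export
wavelet_cycles <- function(plan, f) {
  stopifnot(inherits(plan, "wavelet_plan"))
  cycles_at(f, plan$fmin, plan$fmax, plan$cmin, plan$cmax)
}

#' Wavelet window duration at arbitrary frequencies
#'
#' Duration (seconds) of the effective analysis window, cycles(f) / f. This
#' is the temporal smear a phase estimate at frequency f is subject to.
#'
#' @inheritParams wavelet_cycles
#' @return Durations in seconds.
#' @export
wavelet_window_duration <- function(plan, f) wavelet_cycles(plan, f) / f

# Envelope SD of the Morlet at frequency f. The wavelet's total support is
# its window duration cycles / f: the kernel is truncated at +/- 4 sigma_t
# (where the Gaussian is ~3e-4 of its peak), so sigma_t = cycles / (8 f)
# places the truncation edge exactly at +/- cycles / (2 f).
morlet_sigma_t <- function(f, cycles) cycles / (8 * f)

# Half-support of the truncated kernel in samples.
morlet_half <- function(f, cycles, fs) {
  max(1L, as.integer(ceiling(4 * morlet_sigma_t(f, cycles) * fs)))
}

# Complex Morlet kernel at frequency f: exp(2*pi*i*f*t) under a Gaussian
# envelope spanning cycles/f in total (truncated at +/- 4 sigma_t), and
# L1-normalized so a unit-amplitude cosine at f yields |coefficient| ~ 1.
morlet_kernel <- function(f, cycles, fs) {
  sigma_t <- morlet_sigma_t(f, cycles)
  half <- morlet_half(f, cycles, fs)
  t <- (-half:half) / fs
  env <- exp(-t^2 / (2 * sigma_t^2))
  w <- env * exp(2i * pi * f * t)
  w <- 2 * w / sum(env)
  list(w = w, half = half)
}

#' Morlet wavelet transform
#'
#' Convolves each trial with complex Morlet wavelets at the plan's
#' frequencies (or a subset). Edges where the wavelet support does not fully
#' fit are flagged invalid in the `valid` mask rather than silently zeroed.
#'
#' @param x Numeric matrix, trials x samples (vector = one trial).
#' @param plan A [make_wavelet_plan()] (its `fs` must match the data).
#' @param freqs Optional frequencies (Hz) to evaluate; defaults to the full
#'   plan grid. Values need not lie on the grid; cycle counts follow the
#'   plan's schedule.
#' @param time Optional sample-time vector (seconds) carried to the output.
#' @return List of class `phase_tensor`: `coeffs` (complex array trials x
#'   freqs x samples), `freqs`, `cycles`, `time`, `fs`, and `valid`
#'   (freqs x samples logical mask).
#' @export
wavelet_transform <- function(x, plan, freqs = NULL, time = NULL) {
  stopifnot(inherits(plan, "wavelet_plan"))
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (is.null(freqs)) freqs <- plan$freqs
  if (is.null(time)) time <- attr(x, "time")
  n <- ncol(x)
  cyc <- wavelet_cycles(plan, freqs)
  halves <- vapply(seq_along(freqs), function(j) {
    morlet_half(freqs[j], cyc[j], plan$fs)
  }, integer(1))
  check(n > 2 * max(halves),
        "signal shorter than the wavelet support at the lowest frequency")
  npad <- stats::nextn(n + 2L * max(halves), 2)
  X <- fft_rows(cbind(x + 0i, matrix(0i, nrow(x), npad - n)))
  coeffs <- array(NA_complex_, c(nrow(x), length(freqs), n))
  valid <- matrix(TRUE, length(freqs), n)
  for (j in seq_along(freqs)) {
    k <- morlet_kernel(freqs[j], cyc[j], plan$fs)
    K <- stats::fft(c(k$w, rep(0i, npad - length(k$w))))
    y <- ifft_rows(sweep(X, 2, K, `*`))
    # alignment: kernel peak sits at index k$half + 1 of the kernel
    coeffs[, j, ] <- y[, k$half + seq_len(n), drop = FALSE]
    if (k$half > 0) {
      valid[j, seq_len(min(k$half, n))] <- FALSE
      valid[j, seq.int(max(1L, n - k$half + 1L), n)] <- FALSE
    }
  }
  structure(list(coeffs = coeffs, freqs = freqs, cycles = cyc,
                 time = time, fs = plan$fs, valid = valid),
            class = "phase_tensor")
}

#' Extract phases from a phase tensor
#' @param pt A `phase_tensor` from [wavelet_transform()].
#' @param freq_index,sample_index Optional indices to slice.
#' @return Array of phase angles with the same shape as the slice.
#' @export
tensor_phase <- function(pt, freq_index = NULL, sample_index = NULL) {
  stopifnot(inherits(pt, "phase_tensor"))
  co <- pt$coeffs
  if (!is.null(freq_index)) co <- co[, freq_index, , drop = FALSE]
  if (!is.null(sample_index)) co <- co[, , sample_index, drop = FALSE]
  Arg(co)
}
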