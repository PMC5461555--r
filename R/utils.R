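# Internal helpers shared across modules: deterministic seed derivation,
# column-wise FFTs over the time axis, and input validation.

#' Derive a reproducible sub-seed
#'
#' Folds a base seed and any number of integer indices into a single seed
#' below 2^31, so that nested stochastic steps (per dataset, per frequency,
#' per fold) each get an independent, reproducible stream.
#'
#' @param seed Base integer seed.
#' @param ... Integer indices identifying the sub-stream.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  ks <- c(seed, unlist(list(...)))
  stopifnot(all(is.finite(ks)))
  h <- 0
  for (k in ks) {
    h <- (h * 69069 + (abs(as.numeric(k)) %% 2^31) + 1) %% 2147483647
  }
  as.integer(h)
}

# Run expr with a local RNG state seeded at `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# FFT of each row of a trials x samples matrix, over the time axis.
fft_rows <- function(x) t(stats::mvfft(t(x)))

ifft_rows <- function(x) t(stats::mvfft(t(x), inverse = TRUE)) / ncol(x)

# Frequency (Hz) of each DFT bin for an n-sample signal at rate fs.
fft_freqs <- function(n, fs) {
  k <- 0:(n - 1)
  f <- k * fs / n
  f[f > fs / 2] <- f[f > fs / 2] - fs
  f
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

check <- function(cond, ...) if (!isTRUE(cond)) stop_invalid(...)
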