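test_that("band phase of a pure tone recovers the analytic phase ramp", {
  fs <- 500
  tt <- (0:1499) / fs
  y <- cos(2 * pi * 7.08 * tt + 0.4)
  ph <- hilbert_band_phase(y, fs, 7.08, 1)[1, ]
  truep <- Arg(exp(1i * (2 * pi * 7.08 * tt + 0.4)))
  err <- abs(Arg(exp(1i * (ph - truep))))
  expect_lt(max(err[200:1300]), 1e-2)
})

test_that("band phase rejects an out-of-band tone (two-tone oracle)", {
  fs <- 500
  tt <- (0:1499) / fs
  y <- cos(2 * pi * 7 * tt + 0.3) + cos(2 * pi * 40 * tt + 1.1)
  ph <- hilbert_band_phase(y, fs, 7.08, 1)[1, 300:1200]
  truep <- Arg(exp(1i * (2 * pi * 7 * tt[300:1200] + 0.3)))
  expect_lt(max(abs(Arg(exp(1i * (ph - truep))))), 0.1)
})

test_that("band phase of white noise is marginally uniform (Rayleigh)", {
  cfg <- noise_config(n_trials = 400, seed = 12)
  x <- generate_noise(cfg)
  ph <- phaselat:::band_phase_at(x, cfg$fs, 7.08, 1, 771)
  n <- length(ph)
  R <- Mod(mean(exp(1i * ph)))
  p_rayleigh <- exp(-n * R^2)
  expect_gt(p_rayleigh, 0.01)
})

test_that("band_phase_at matches the full transform at selected samples", {
  cfg <- noise_config(n_trials = 20, seed = 13)
  x <- generate_noise(cfg)
  idx <- c(100, 771, 1400)
  fast <- phaselat:::band_phase_at(x, cfg$fs, 10, 1, idx)
  full <- hilbert_band_phase(x, cfg$fs, 10, 1)[, idx]
  expect_lt(max(abs(Arg(exp(1i * (fast - full))))), 1e-9)
})

test_that("band preconditions are enforced", {
  x <- matrix(rnorm(100), 1)
  expect_error(hilbert_band_phase(x, 500, 0.5, 1), "above 0 Hz")
  expect_error(hilbert_band_phase(x, 500, 249.5, 1), "Nyquist")
})

test_that("wavelet plan is geometric in frequency and cycles", {
  plan <- make_wavelet_plan()
  expect_length(plan$freqs, 50)
  expect_equal(plan$freqs[1], 3)
  expect_equal(plan$freqs[50], 100)
  ratios <- diff(log(plan$freqs))
  expect_lt(diff(range(ratios)), 1e-12)
  expect_equal(plan$cycles[1], 3)
  expect_equal(plan$cycles[50], 8)
  cr <- diff(log(plan$cycles))
  expect_lt(diff(range(cr)), 1e-12)
  expect_error(make_wavelet_plan(fmin = 10, fmax = 5), "below fmax")
  expect_error(make_wavelet_plan(cmin = 9, cmax = 8), "exceed")
  expect_error(make_wavelet_plan(fmax = 300, fs = 500), "Nyquist")
})

test_that("window durations follow cycles(f)/f", {
  plan <- make_wavelet_plan()
  expect_equal(wavelet_window_duration(plan, 3), 1)
  expect_equal(wavelet_window_duration(plan, 100), 0.08)
  f <- 12.3
  expect_equal(wavelet_window_duration(plan, f),
               wavelet_cycles(plan, f) / f)
})

test_that("wavelet responds to a delta at the right sample", {
  fs <- 500
  x <- numeric(1500)
  x[800] <- 1
  plan <- make_wavelet_plan(fs = fs)
  for (f in c(5, 20, 80)) {
    pt <- wavelet_transform(x, plan, freqs = f)
    expect_equal(which.max(abs(pt$coeffs[1, 1, ])), 800)
  }
})

test_that("wavelet phase and amplitude of a cosine are exact", {
  fs <- 500
  tt <- (0:1499) / fs
  plan <- make_wavelet_plan(fs = fs)
  for (f in c(7.08, 39.44)) {
    y <- cos(2 * pi * f * tt + 0.7)
    pt <- wavelet_transform(y, plan, freqs = f)
    mid <- 400:1100
    truep <- Arg(exp(1i * (2 * pi * f * tt[mid] + 0.7)))
    # the +/-4 sigma envelope truncation leaves ~3e-5 of phase ripple
    expect_lt(max(abs(Arg(exp(1i * (Arg(pt$coeffs[1, 1, mid]) - truep))))),
              1e-4)
    expect_lt(max(abs(abs(pt$coeffs[1, 1, mid]) - 1)), 0.05)
  }
})

test_that("the valid mask flags wavelet edge samples", {
  plan <- make_wavelet_plan(fs = 500)
  x <- matrix(rnorm(2 * 1500), 2)
  pt <- wavelet_transform(x, plan, freqs = c(3, 100))
  half3 <- phaselat:::morlet_half(3, wavelet_cycles(plan, 3), 500)
  expect_false(any(pt$valid[1, 1:half3]))
  expect_true(all(pt$valid[1, (half3 + 1):(1500 - half3)]))
  expect_false(any(pt$valid[1, (1500 - half3 + 1):1500]))
  expect_gt(sum(pt$valid[2, ]), sum(pt$valid[1, ])) # shorter kernel at 100 Hz
  expect_error(wavelet_transform(matrix(rnorm(100), 1), plan),
               "shorter than the wavelet support")
})

test_that("the kernel support equals the window duration", {
  fs <- 500
  for (f in c(3, 10, 100)) {
    cyc <- wavelet_cycles(make_wavelet_plan(fs = fs), f)
    k <- phaselat:::morlet_kernel(f, cyc, fs)
    support_s <- (2 * k$half + 1) / fs
    # half = ceiling(4 sigma fs) can overshoot by up to a sample per side,
    # plus the centre sample
    expect_lt(abs(support_s - cyc / f), 3.5 / fs)
  }
})

test_that("tensor_phase slices the coefficient array", {
  plan <- make_wavelet_plan(fs = 500)
  x <- matrix(rnorm(2 * 1500), 2)
  pt <- wavelet_transform(x, plan, freqs = c(6, 10))
  ph <- tensor_phase(pt)
  expect_equal(dim(ph), c(2, 2, 1500))
  ph1 <- tensor_phase(pt, freq_index = 2, sample_index = 100:110)
  expect_equal(dim(ph1), c(2, 1, 11))
  expect_equal(ph1[1, 1, 1], Arg(pt$coeffs[1, 2, 100]))
})
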