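test_that("irf objects validate their geometry", {
  k <- synthetic_irf(n_channels = 3)
  expect_s3_class(k, "irf")
  expect_equal(nrow(k$kernel), 3)
  expect_equal(k$lags[1], 0)
  expect_gt(max(abs(k$kernel[1, ])), max(abs(k$kernel[3, ]))) # gain taper
  expect_error(irf(matrix(1, 1, 3), lags = c(-0.1, 0, 0.1), fs = 10),
               "at or after 0")
  expect_error(irf(matrix(1, 1, 3), lags = c(0, 0.1), fs = 10), "align")
})

test_that("reconstruct_eeg equals direct causal convolution", {
  set.seed(2)
  kern <- irf(matrix(c(0.5, -0.2, 0.1), 1), lags = c(0, 1, 2) / 10, fs = 10)
  x <- runif(30)
  rec <- reconstruct_eeg(kern, x)
  xc <- x - mean(x)
  manual <- vapply(seq_along(x), function(i) {
    s <- 0
    for (l in 0:2) if (i - l >= 1) s <- s + kern$kernel[1, l + 1] * xc[i - l]
    s
  }, numeric(1))
  expect_equal(as.vector(rec), manual, tolerance = 1e-10)
})

test_that("a constant mean-gray sequence reconstructs to exactly zero", {
  kern <- synthetic_irf(n_channels = 2)
  rec <- reconstruct_eeg(kern, rep(0.5, 400))
  expect_true(all(abs(rec) < 1e-12))
})

test_that("reconstruction is causal and target frames evoke nothing", {
  # two sequences identical up to frame 200, diverging after: the
  # reconstructions must agree strictly before the divergence point
  set.seed(3)
  kern <- synthetic_irf(n_channels = 1)
  s1 <- runif(500)
  s2 <- s1
  s2[201:230] <- s1[sample(201:230)] # same values, same mean
  r1 <- reconstruct_eeg(kern, s1)
  r2 <- reconstruct_eeg(kern, s2)
  expect_lt(max(abs(r1[1, 1:200] - r2[1, 1:200])),
            1e-9 * stats::sd(r1[1, ]))
  expect_gt(max(abs(r1[1, 201:500] - r2[1, 201:500])), 0.01)
})

test_that("estimate_irf recovers the generating kernel without noise", {
  cfg <- observer_config(n_sequences = 8, noise_sd = 0,
                         irf_true = synthetic_irf(n_channels = 2), seed = 41)
  o <- generate_observer(cfg)
  est <- estimate_irf(o$recorded, o$sequences, o$fs)
  L <- length(o$irf_true$lags)
  for (ch in 1:2) {
    expect_gt(stats::cor(est$kernel[ch, 1:L], o$irf_true$kernel[ch, ]),
              0.99)
  }
  expect_equal(est$lags[1], 0)
})

test_that("averaged reconstructed epochs around targets are flat", {
  o <- tiny_cohort()[[1]]
  est <- estimate_irf(o$recorded, o$sequences, o$fs)
  recon <- reconstruct_eeg(est, o$sequences)
  es <- suppressMessages(
    epoch_and_erp(recon, o$events, o$fs, window = c(-0.3, 0.3),
                  baseline = NULL))
  # no target-evoked deflection: the trial average stays within the
  # sampling noise of a zero-mean average over n epochs (a genuine evoked
  # response would be on the single-trial scale, sqrt(n) larger)
  n_ep <- dim(es$epochs)[1]
  expect_lt(max(abs(es$erp$overall)),
            4 * stats::sd(es$epochs) / sqrt(n_ep))
})

test_that("epoch_and_erp recovers an injected target-locked deflection", {
  set.seed(6)
  fs <- 160
  sig <- array(rnorm(4 * 1 * 1000, 0, 0.05), c(4, 1, 1000))
  ev <- data.frame(sequence_id = rep(1:4, each = 2),
                   frame_index = rep(c(300, 600), 4),
                   outcome = rep(c(1L, 0L), 4))
  lat_frames <- 12
  for (k in seq_len(nrow(ev))) {
    sig[ev$sequence_id[k], 1, ev$frame_index[k] + lat_frames] <-
      sig[ev$sequence_id[k], 1, ev$frame_index[k] + lat_frames] + 5
  }
  es <- epoch_and_erp(sig, ev, fs, window = c(-0.2, 0.3),
                      baseline = c(-0.2, 0))
  expect_equal(dim(es$epochs)[1], 8)
  expect_equal(es$time[which.max(es$erp$overall[1, ])], lat_frames / fs)
  # per-epoch baseline is removed
  bidx <- es$time >= -0.2 & es$time <= 0
  expect_lt(max(abs(apply(es$epochs[, 1, bidx], 1, mean))), 1e-12)
  expect_true(all(c("outcome_0", "outcome_1") %in% names(es$erp)))
  # events too close to an edge are dropped with a message
  ev_edge <- rbind(ev, data.frame(sequence_id = 1, frame_index = 5,
                                  outcome = 1L))
  expect_message(epoch_and_erp(sig, ev_edge, fs, window = c(-0.2, 0.3)),
                 "dropped")
})

test_that("band_filter passes in-band and rejects out-of-band tones", {
  fs <- 160
  tt <- (0:1599) / fs
  x <- sin(2 * pi * 10 * tt)
  y <- phaselat:::band_filter(x, fs, c(7, 14))
  expect_gt(stats::sd(y) / stats::sd(x), 0.9)
  z <- phaselat:::band_filter(sin(2 * pi * 40 * tt), fs, c(7, 14))
  expect_lt(stats::sd(z), 0.05)
})

test_that("make_folds partitions the indices", {
  f <- phaselat:::make_folds(17, 4, seed = 9)
  expect_length(f, 4)
  expect_setequal(unlist(f), 1:17)
  expect_equal(sum(lengths(f)), 17)
})

test_that("cross-validated correlation approaches 1 as noise vanishes", {
  coh_clean <- make_observer_cohort(n_subjects = 3, n_sequences = 8,
                                    n_channels = 2, noise_sd = 0.01,
                                    seed = 51)
  cv_clean <- crossval_model_correlation(coh_clean, model = "irf", k = 4,
                                         seed = 51)
  expect_true(all(cv_clean$per_channel$mean_r > 0.95))
  expect_true(all(cv_clean$per_channel$sig))
  coh_noisy <- make_observer_cohort(n_subjects = 3, n_sequences = 8,
                                    n_channels = 2, noise_sd = 2, seed = 51)
  cv_noisy <- crossval_model_correlation(coh_noisy, model = "irf", k = 4,
                                         seed = 51)
  expect_true(all(cv_noisy$per_channel$mean_r <
                    cv_clean$per_channel$mean_r))
  expect_equal(dim(cv_clean$per_subject_z), c(3, 2))
  expect_error(crossval_model_correlation(coh_clean, k = 1), ">= 2")
})

test_that("the ERP comparison model runs through the same pipeline", {
  cv <- crossval_model_correlation(tiny_cohort(), model = "erp", k = 3,
                                   seed = 52)
  expect_s3_class(cv, "cv_corr_result")
  expect_equal(cv$model, "erp")
  expect_true(all(is.finite(cv$per_channel$mean_z)))
})

test_that("classification image detects a luminance-outcome dependence", {
  set.seed(61)
  fs <- 160
  n_seq <- 30
  seqs <- matrix(runif(n_seq * 800), n_seq, 800)
  ev <- data.frame(sequence_id = rep(1:n_seq, each = 2),
                   frame_index = rep(c(250, 550), n_seq))
  lag <- 4
  lum <- seqs[cbind(ev$sequence_id, ev$frame_index + lag)]
  ev$outcome <- as.integer(lum > stats::median(lum))
  ci <- classification_image(list(list(sequences = seqs, events = ev,
                                       fs = fs)),
                             window = c(-0.1, 0.1))
  at <- ci[abs(ci$time - lag / fs) < 1e-9, ]
  expect_true(at$sig)
  expect_gt(at$mean_hit, at$mean_miss)
  off <- ci[abs(ci$time + 0.05) < 0.004, ]
  expect_true(all(!off$sig))
})

test_that("largest_cluster_2d picks the biggest 4-connected component", {
  m <- matrix(FALSE, 5, 6)
  m[1, 1] <- TRUE                     # singleton
  m[3, 2:4] <- TRUE                   # size 3
  m[4, 3] <- TRUE                     # joined -> size 4
  m[5, 6] <- TRUE
  cl <- phaselat:::largest_cluster_2d(m)
  expect_equal(sum(cl), 4)
  expect_true(all(cl[3, 2:4]) && cl[4, 3])
  expect_false(cl[1, 1])
  expect_equal(sum(phaselat:::largest_cluster_2d(matrix(FALSE, 2, 2))), 0)
})

test_that("fisher z transform round-trips", {
  r <- c(-0.9, -0.2, 0, 0.5, 0.99)
  expect_equal(fisher_z_inv(fisher_z(r)), r)
})

test_that("grand POS on reconstructions returns a coherent result object", {
  res <- suppressMessages(
    phase_opposition_on_reconstruction(tiny_cohort(), n_perm = 100,
                                       n_resample = 2000,
                                       topo_resample = 1000, seed = 71))
  expect_s3_class(res, "wn_pos_result")
  expect_equal(dim(res$sig), c(length(res$freqs), length(res$times)))
  expect_length(res$times, 256) # -800..+794 ms at 160 Hz
  expect_true(all(res$freqs <= 80))
  expect_s3_class(res$grand, "pos_result")
  if (!is.null(res$peak)) {
    expect_true(res$cluster[which.min(abs(res$freqs - res$peak$freq)),
                            which.min(abs(res$times - res$peak$time))])
    expect_equal(nrow(res$topography), 2)
  }
})
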