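# White-noise paradigm pipeline: impulse-response estimation by
# cross-correlation, reconstruction by convolution, epoching and evoked
# responses, cross-validated reconstruction-vs-recording correlation,
# classification images, and grand-average phase opposition on the
# reconstructed signals.

#' Fisher Z transform and its inverse
#'
#' `Z = 0.5 * ln((1 + r) / (1 - r))`; variance-stabilizing transform for
#' correlation coefficients.
#'
#' @param r Correlation coefficients in (-1, 1).
#' @return Transformed values.
#' @export
fisher_z <- function(r) 0.5 * log((1 + r) / (1 - r))

#' @rdname fisher_z
#' @param z Fisher-transformed values.
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Estimate the impulse response by cross-correlation
#'
#' Per channel, the lagged cross-correlation between the mean-centred
#' stimulus and the recorded signal, pooled over sequences and normalized
#' by `N * var(stimulus)` so the kernel has regression-coefficient units
#' (signal units per luminance unit); with that scaling, convolving the
#' estimate with the stimulus reproduces the driven signal amplitude.
#'
#' @param recorded Array sequences x channels x samples (or matrix channels
#'   x samples for one sequence).
#' @param sequences Luminance matrix sequences x frames on the same
#'   sampling grid.
#' @param fs Sampling rate, Hz.
#' @param lag_window Lag range, seconds (start >= 0; default 0-0.75 s).
#' @return An [irf()] object.
#' @export
estimate_irf <- function(recorded, sequences, fs,
                         lag_window = c(0, 0.75)) {
  if (is.matrix(recorded)) recorded <- array(recorded, c(1, dim(recorded)))
  if (is.vector(sequences)) sequences <- matrix(sequences, nrow = 1)
  check(dim(recorded)[1] == nrow(sequences) &&
          dim(recorded)[3] == ncol(sequences),
        "recorded data and stimulus sequences must share the sampling grid")
  n <- ncol(sequences)
  n_ch <- dim(recorded)[2]
  lag_idx <- round(lag_window[1] * fs):round(lag_window[2] * fs)
  check(lag_idx[1] >= 0, "lag window must start at or after 0")
  npad <- stats::nextn(2 * n, 2)
  acc <- matrix(0, n_ch, length(lag_idx))
  var_acc <- 0
  for (s in seq_len(nrow(sequences))) {
    xc <- sequences[s, ] - mean(sequences[s, ])
    var_acc <- var_acc + sum(xc^2)
    Xc <- Conj(stats::fft(c(xc, rep(0, npad - n))))
    for (ch in seq_len(n_ch)) {
      y <- recorded[s, ch, ]
      cc <- Re(stats::fft(stats::fft(c(y, rep(0, npad - n))) * Xc,
                          inverse = TRUE)) / npad
      # cc[l + 1] = sum_t x[t] * y[t + l] for l >= 0
      acc[ch, ] <- acc[ch, ] + cc[lag_idx + 1]
    }
  }
  kernel <- acc / var_acc
  irf(kernel, lags = lag_idx / fs, fs = fs)
}

#' Reconstruct the stimulus-driven signal by convolution
#'
#' Causal convolution of the estimated kernel with the mean-centred
#' luminance sequence; lag 0 of the kernel multiplies the current frame.
#' Because targets and their suppression windows carry exactly the
#' sequence's mean-gray luminance, the reconstruction is bit-identical
#' whether or not targets are present: it contains no target-evoked
#' response.
#'
#' @param irf An [irf()] object.
#' @param sequence Luminance vector (one sequence) or matrix sequences x
#'   frames.
#' @return Matrix channels x frames, or array sequences x channels x frames
#'   for matrix input.
#' @export
reconstruct_eeg <- function(irf, sequence) {
  stopifnot(inherits(irf, "irf"))
  if (is.matrix(sequence)) {
    out <- array(0, c(nrow(sequence), nrow(irf$kernel), ncol(sequence)))
    for (s in seq_len(nrow(sequence))) {
      out[s, , ] <- reconstruct_eeg(irf, sequence[s, ])
    }
    return(out)
  }
  xc <- sequence - mean(sequence)
  t(vapply(seq_len(nrow(irf$kernel)),
           function(ch) conv_causal(irf$kernel[ch, ], xc),
           numeric(length(sequence))))
}

#' Epoch a continuous signal around events and compute evoked responses
#'
#' Cuts epochs on `window` around each event, subtracts the per-epoch,
#' per-channel baseline mean over `baseline`, and averages per outcome
#' group. Events whose epoch would cross a sequence edge are dropped with a
#' message. With the default 160 Hz grid and window -800 to +794 ms, epochs
#' are 256 samples with sample times -800 + k * 6.25 ms.
#'
#' @param signal Array sequences x channels x samples (matrix = one
#'   sequence, channels x samples).
#' @param events Data frame with `sequence_id`, `frame_index` and
#'   (optionally) `outcome`.
#' @param fs Sampling rate, Hz.
#' @param window Epoch window, seconds.
#' @param baseline Baseline window, seconds (NULL skips baseline removal).
#' @return Object of class `epoch_set`: `epochs` (trials x channels x
#'   samples), `time` (s), `outcomes`, `erp` (list: `overall`, and one
#'   entry per outcome level; each channels x samples), `fs`.
#' @export
epoch_and_erp <- function(signal, events, fs,
                          window = c(-0.800, 0.794),
                          baseline = c(-0.200, 0)) {
  if (is.matrix(signal)) signal <- array(signal, c(1, dim(signal)))
  n_samp <- dim(signal)[3]
  n_ch <- dim(signal)[2]
  rel <- round(window[1] * fs):round(window[2] * fs)
  keep <- events$frame_index + min(rel) >= 1 &
    events$frame_index + max(rel) <= n_samp
  if (any(!keep)) {
    message(sprintf("%d event(s) too close to a sequence edge dropped",
                    sum(!keep)))
  }
  ev <- events[keep, , drop = FALSE]
  ep <- array(0, c(nrow(ev), n_ch, length(rel)))
  for (k in seq_len(nrow(ev))) {
    ep[k, , ] <- signal[ev$sequence_id[k], ,
                        ev$frame_index[k] + rel, drop = FALSE]
  }
  time <- rel / fs
  if (!is.null(baseline)) {
    bidx <- which(time >= baseline[1] & time <= baseline[2])
    bl <- apply(ep[, , bidx, drop = FALSE], c(1, 2), mean)
    ep <- ep - array(bl, dim(ep))  # recycles over the sample dimension
  }
  outcomes <- if ("outcome" %in% names(ev)) ev$outcome else NULL
  erp <- list(overall = apply(ep, c(2, 3), mean))
  if (!is.null(outcomes)) {
    for (lv in sort(unique(outcomes))) {
      erp[[paste0("outcome_", lv)]] <-
        apply(ep[outcomes == lv, , , drop = FALSE], c(2, 3), mean)
    }
  }
  structure(list(epochs = ep, time = time, outcomes = outcomes,
                 events = ev, erp = erp, fs = fs),
            class = "epoch_set")
}

# Zero-phase band filter (frequency-domain mask with raised-cosine
# transitions whose width is 25% of the corresponding band edge).
band_filter <- function(x, fs, band) {
  n <- length(x)
  f <- abs(fft_freqs(n, fs))
  lo <- band[1]; hi <- band[2]
  check(hi < fs / 2, "band must lie below Nyquist")
  m <- numeric(n)
  tw_lo <- 0.25 * lo; tw_hi <- 0.25 * hi
  m[f >= lo & f <= hi] <- 1
  rl <- f < lo & f > lo - tw_lo
  m[rl] <- 0.5 * (1 + cos(pi * (lo - f[rl]) / tw_lo))
  rh <- f > hi & f < hi + tw_hi
  m[rh] <- 0.5 * (1 + cos(pi * (f[rh] - hi) / tw_hi))
  Re(stats::fft(stats::fft(x) * m, inverse = TRUE)) / n
}

# Contiguous fold assignment after a seeded shuffle of sequence indices.
make_folds <- function(n, k, seed) {
  ord <- with_seed(seed, sample.int(n))
  split(ord, cut(seq_len(n), k, labels = FALSE))
}

#' Cross-validated correlation between recorded and model-reconstructed EEG
#'
#' For each subject (an `observer_dataset`), sequences are split into `k`
#' folds; the model — the impulse response (`"irf"`), or the target-evoked
#' potential convolved with a target-onset impulse train (`"erp"`) — is
#' fitted on the training folds and used to reconstruct the held-out
#' sequences, which are Pearson-correlated with the recording per channel.
#' Fold correlations are Fisher-Z transformed and averaged per subject;
#' with several subjects, a one-sample t test against zero is run per
#' channel with Benjamini-Hochberg correction across channels. With a list
#' of subjects, trial counts are first subsampled to the smallest subject.
#'
#' @param observers An `observer_dataset` or a list of them (subjects).
#' @param model `"irf"` or `"erp"`.
#' @param k Number of folds (>= 2).
#' @param band Optional frequency band (Hz, length 2); both signals are
#'   band-filtered (zero phase) before correlating.
#' @param lag_window Lag window for IRF estimation, seconds.
#' @param holdout If `FALSE`, train and test on the same sequences
#'   (circular; only for quantifying the leakage the cross-validation
#'   guards against).
#' @param seed Integer seed (fold shuffling, subsampling).
#' @return Object of class `cv_corr_result`: `per_channel` data frame
#'   (`channel`, `mean_z`, `mean_r`, and with > 1 subject `t`, `p`, `sig`),
#'   `per_subject_z` (subjects x channels), `k`, `band`.
#' @export
crossval_model_correlation <- function(observers, model = c("irf", "erp"),
                                       k = 10, band = NULL,
                                       lag_window = c(0, 0.75),
                                       holdout = TRUE, seed = 1) {
  model <- match.arg(model)
  check(k >= 2, "k must be >= 2")
  if (inherits(observers, "observer_dataset")) observers <- list(observers)
  n_seq_min <- min(vapply(observers, function(o) nrow(o$sequences),
                          integer(1)))
  z_subj <- NULL
  for (si in seq_along(observers)) {
    o <- observers[[si]]
    use <- with_seed(derive_seed(seed, si, 1L),
                     sort(sample.int(nrow(o$sequences), n_seq_min)))
    folds <- make_folds(n_seq_min, k, derive_seed(seed, si, 2L))
    n_ch <- dim(o$recorded)[2]
    zf <- matrix(NA_real_, k, n_ch)
    for (fi in seq_len(k)) {
      test <- use[folds[[fi]]]
      train <- if (holdout) setdiff(use, test) else test
      recon <- reconstruct_cv(o, train, test, model, lag_window)
      for (ch in seq_len(n_ch)) {
        rec <- as.vector(aperm(o$recorded[test, ch, , drop = FALSE],
                               c(3, 1, 2)))
        mod_ <- as.vector(aperm(recon[, ch, , drop = FALSE], c(3, 1, 2)))
        if (!is.null(band)) {
          rec <- band_filter(rec, o$fs, band)
          mod_ <- band_filter(mod_, o$fs, band)
        }
        r <- stats::cor(rec, mod_)
        r <- max(min(r, 1 - 1e-12), -1 + 1e-12)
        zf[fi, ch] <- fisher_z(r)
      }
    }
    z_subj <- rbind(z_subj, colMeans(zf))
  }
  per_channel <- data.frame(channel = seq_len(ncol(z_subj)),
                            mean_z = colMeans(z_subj),
                            mean_r = fisher_z_inv(colMeans(z_subj)))
  if (nrow(z_subj) > 1) {
    tt <- apply(z_subj, 2, function(zz) {
      ht <- stats::t.test(zz, mu = 0)
      c(ht$statistic, ht$p.value)
    })
    per_channel$t <- tt[1, ]
    per_channel$p <- tt[2, ]
    per_channel$sig <- correct_multiple(tt[2, ], "fdr_bh", 0.05)
  }
  structure(list(per_channel = per_channel, per_subject_z = z_subj,
                 k = as.integer(k), band = band, model = model),
            class = "cv_corr_result")
}

# Model-based reconstruction of the test sequences from training data.
reconstruct_cv <- function(o, train, test, model, lag_window) {
  n_ch <- dim(o$recorded)[2]
  if (model == "irf") {
    est <- estimate_irf(o$recorded[train, , , drop = FALSE],
                        o$sequences[train, , drop = FALSE],
                        fs = o$fs, lag_window = lag_window)
    reconstruct_eeg(est, o$sequences[test, , drop = FALSE])
  } else {
    ev_train <- o$events[o$events$sequence_id %in% train, , drop = FALSE]
    es <- epoch_and_erp(o$recorded, ev_train, o$fs,
                        window = c(0, lag_window[2]), baseline = NULL)
    erp <- es$erp$overall  # channels x samples
    out <- array(0, c(length(test), n_ch, ncol(o$sequences)))
    for (ti in seq_along(test)) {
      onsets <- numeric(ncol(o$sequences))
      onsets[o$events$frame_index[o$events$sequence_id == test[ti]]] <- 1
      for (ch in seq_len(n_ch)) {
        out[ti, ch, ] <- conv_causal(erp[ch, ], onsets)
      }
    }
    out
  }
}

#' Classification image: stimulus luminance around hits vs misses
#'
#' For each time point around the target, compares the luminance of the
#' stimulus sequence preceding/following detected vs missed targets with an
#' independent-samples t test, then applies Benjamini-Hochberg correction
#' across time points (and subjects, when a list is given). Time points
#' with zero luminance variance in both groups (e.g. the suppression
#' window, where every frame is mean gray) are excluded.
#'
#' @param observers An `observer_dataset` or list of them.
#' @param window Time window around the target, seconds.
#' @param alpha FDR level.
#' @return Data frame: `subject`, `time`, `mean_hit`, `mean_miss`, `t`,
#'   `p`, `sig`.
#' @export
classification_image <- function(observers, window = c(-0.3, 0.3),
                                 alpha = 0.05) {
  if (inherits(observers, "observer_dataset")) observers <- list(observers)
  out <- list()
  for (si in seq_along(observers)) {
    o <- observers[[si]]
    lum <- array(o$sequences, c(nrow(o$sequences), 1, ncol(o$sequences)))
    es <- epoch_and_erp(lum, o$events, o$fs, window = window,
                        baseline = NULL)
    check(length(unique(es$outcomes)) == 2,
          "both outcome classes must be present")
    h <- es$epochs[es$outcomes == 1L, 1, , drop = FALSE][, 1, ]
    m <- es$epochs[es$outcomes == 0L, 1, , drop = FALSE][, 1, ]
    nh <- nrow(h); nm <- nrow(m)
    vh <- apply(h, 2, stats::var)
    vm <- apply(m, 2, stats::var)
    se <- sqrt(vh / nh + vm / nm)
    tstat <- (colMeans(h) - colMeans(m)) / se
    df <- (vh / nh + vm / nm)^2 /
      ((vh / nh)^2 / (nh - 1) + (vm / nm)^2 / (nm - 1))
    p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
    out[[si]] <- data.frame(subject = si, time = es$time,
                            mean_hit = colMeans(h), mean_miss = colMeans(m),
                            t = tstat, p = p)
  }
  res <- do.call(rbind, out)
  res$sig <- FALSE
  ok <- is.finite(res$p)
  res$sig[ok] <- correct_multiple(res$p[ok], "fdr_bh", alpha)
  res
}

# Largest 4-connected cluster of TRUE cells in a logical matrix; returns a
# logical matrix marking the cluster (all FALSE if no TRUE cell).
largest_cluster_2d <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      stack <- list(c(i, j))
      lab[i, j] <- cur
      while (length(stack)) {
        c0 <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          ii <- c0[1] + d[1]; jj <- c0[2] + d[2]
          if (ii >= 1 && ii <= nrow(mask) && jj >= 1 && jj <= ncol(mask) &&
              mask[ii, jj] && lab[ii, jj] == 0L) {
            lab[ii, jj] <- cur
            stack[[length(stack) + 1L]] <- c(ii, jj)
          }
        }
      }
    }
  }
  if (cur == 0L) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0L], cur)
  lab == which.max(sizes)
}

#' Grand-average phase opposition on reconstructed signals
#'
#' The end-to-end analysis of the white-noise paradigm: per subject, the
#' impulse response is estimated from the recorded data, the stimulus-driven
#' signal is reconstructed by convolution, epoched around targets, and
#' wavelet-decomposed (two-to-eight-cycle schedule, frequencies capped at
#' `fmax`); per channel, observed and label-shuffle surrogate POS values are
#' computed over all time-frequency cells and summed across channels, then
#' aggregated across subjects by grand-average resampling. FDR (level
#' `alpha`) across time and frequency defines the significant region; its
#' largest 4-connected cluster gives the peak frequency/latency, and a
#' channel topography is extracted by re-summing POS over the cluster cells
#' with `topo_resample` surrogate draws. Finally the phase-binned
#' performance curve at the peak cell is computed on `perf_channel`.
#'
#' @param observers List of `observer_dataset` subjects (or a single one).
#' @param plan Wavelet plan (defaults to the two-to-eight-cycle schedule at
#'   the observers' sampling rate).
#' @param fmax Upper frequency cap, Hz.
#' @param epoch_window,baseline Epoching windows, seconds.
#' @param n_perm Per-subject label shuffles.
#' @param n_resample Grand-average surrogate draws.
#' @param topo_resample Surrogate draws for the topography stage.
#' @param alpha FDR level.
#' @param perf_channel Channel for the phase-binned performance curve.
#' @param use_true_irf Use the generator's true kernel instead of estimating
#'   it (diagnostics).
#' @param seed Integer seed.
#' @return List of class `wn_pos_result`: `grand` (`pos_result`), `freqs`,
#'   `times` (s), `sig` and `cluster` (freq x time logical), `peak`
#'   (list: freq, time, z, p), `topography` (data frame channel, z, p),
#'   `performance` (`phase_bin_curve`).
#' @export
phase_opposition_on_reconstruction <- function(observers,
                                               plan = NULL,
                                               fmax = 80,
                                               epoch_window = c(-0.8, 0.794),
                                               baseline = NULL,
                                               n_perm = 200,
                                               n_resample = 20000,
                                               topo_resample = 10000,
                                               alpha = 0.05,
                                               perf_channel = 1,
                                               use_true_irf = FALSE,
                                               seed = 1) {
  if (inherits(observers, "observer_dataset")) observers <- list(observers)
  fs <- observers[[1]]$fs
  if (is.null(plan)) {
    plan <- make_wavelet_plan(fmin = 3, fmax = min(100, fs / 2 - 1),
                              n_freqs = 50, cmin = 2, cmax = 8, fs = fs)
  }
  freqs <- plan$freqs[plan$freqs <= fmax]
  ns <- length(observers)
  obs_cells <- NULL
  surr_cells <- vector("list", ns)
  phases_peak <- vector("list", ns)
  tensors <- vector("list", ns)
  outcomes <- vector("list", ns)
  times <- NULL
  for (si in seq_len(ns)) {
    o <- observers[[si]]
    est <- if (use_true_irf) o$irf_true else {
      estimate_irf(o$recorded, o$sequences, fs)
    }
    recon <- reconstruct_eeg(est, o$sequences)
    es <- epoch_and_erp(recon, o$events, fs, window = epoch_window,
                        baseline = baseline)
    n_ch <- dim(es$epochs)[2]
    outcomes[[si]] <- es$outcomes
    # per-channel wavelet phases: trials x freqs x times
    tens <- lapply(seq_len(n_ch), function(ch) {
      wavelet_transform(es$epochs[, ch, ], plan, freqs = freqs,
                        time = es$time)
    })
    tensors[[si]] <- tens
    times <- es$time
    nt <- length(times)
    m <- length(freqs) * nt
    obs_s <- numeric(m)
    surr_s <- matrix(0, n_perm, m)
    for (ch in seq_len(n_ch)) {
      ph <- Arg(tens[[ch]]$coeffs)
      dim(ph) <- c(dim(ph)[1], m)   # trials x (freq*time) cells
      sp <- surrogate_pos_raw(ph, es$outcomes, n_perm,
                              derive_seed(seed, si, ch))
      obs_s <- obs_s + sp$obs
      surr_s <- surr_s + sp$surr
    }
    obs_cells <- rbind(obs_cells, obs_s)
    surr_cells[[si]] <- surr_s
  }
  grand <- grand_average_pos(obs_cells, surr_cells,
                             n_resample = n_resample,
                             seed = derive_seed(seed, 101L))
  sig <- matrix(correct_multiple(grand$p, "fdr_bh", alpha),
                length(freqs), length(times))
  # exclude wavelet edge cells
  valid <- tensors[[1]][[1]]$valid
  sig <- sig & valid
  cluster <- largest_cluster_2d(sig)
  zmat <- matrix(grand$z, length(freqs), length(times))
  peak <- NULL
  topo <- NULL
  perf <- NULL
  if (any(cluster)) {
    zin <- ifelse(cluster, zmat, -Inf)
    pk <- arrayInd(which.max(zin), dim(zin))
    peak <- list(freq = freqs[pk[1]], time = times[pk[2]],
                 z = zmat[pk[1], pk[2]],
                 p = matrix(grand$p, length(freqs), length(times))[pk[1],
                                                                   pk[2]])
    # topography: per-channel POS summed over cluster cells and subjects
    cells <- which(as.vector(cluster))
    n_ch <- length(tensors[[1]])
    topo_obs <- matrix(0, ns, n_ch)
    topo_surr <- lapply(seq_len(ns), function(si) matrix(0, n_perm, n_ch))
    for (si in seq_len(ns)) for (ch in seq_len(n_ch)) {
      ph <- Arg(tensors[[si]][[ch]]$coeffs)
      dim(ph) <- c(dim(ph)[1], length(freqs) * length(times))
      sp <- surrogate_pos_raw(ph[, cells, drop = FALSE], outcomes[[si]],
                              n_perm, derive_seed(seed, si, ch, 5L))
      topo_obs[si, ch] <- sum(sp$obs)
      topo_surr[[si]][, ch] <- rowSums(sp$surr)
    }
    gt <- grand_average_pos(topo_obs, topo_surr,
                            n_resample = topo_resample,
                            seed = derive_seed(seed, 102L))
    topo <- data.frame(channel = seq_len(n_ch), z = gt$z, p = gt$p)
    # phase-binned performance at the peak cell on perf_channel
    ph_all <- unlist(lapply(seq_len(ns), function(si) {
      Arg(tensors[[si]][[perf_channel]]$coeffs[, pk[1], pk[2]])
    }))
    hit_all <- unlist(outcomes)
    perf <- phase_binned_performance(ph_all, hit_all)
  }
  structure(list(grand = grand, freqs = freqs, times = times, sig = sig,
                 cluster = cluster, peak = peak, topography = topo,
                 performance = perf),
            class = "wn_pos_result")
}

# Observed and surrogate POS for a trials x cells phase matrix without the
# z/p step (shared by the grand-average pipeline).
surrogate_pos_raw <- function(phases, labels, n_perm, seed) {
  labels <- as.integer(labels)
  n <- nrow(phases)
  na <- sum(labels == 1L)
  nb <- n - na
  check(na > 0 && nb > 0, "both trial groups must be present")
  U <- exp(1i * phases)
  tot <- colSums(U)
  itpc_all <- Mod(tot) / n
  obs_a <- colSums(U[labels == 1L, , drop = FALSE])
  obs <- Mod(obs_a) / na + Mod(tot - obs_a) / nb - 2 * itpc_all
  L <- matrix(0, n_perm, n)
  idx <- with_seed(seed, replicate(n_perm, sample.int(n, na)))
  L[cbind(rep(seq_len(n_perm), each = na), as.vector(idx))] <- 1
  re_a <- L %*% Re(U)
  im_a <- L %*% Im(U)
  surr <- sqrt(re_a^2 + im_a^2) / na +
    sqrt(sweep(re_a, 2, Re(tot), function(a, s) s - a)^2 +
         sweep(im_a, 2, Im(tot), function(a, s) s - a)^2) / nb
  surr <- sweep(surr, 2, 2 * itpc_all, `-`)
  list(obs = obs, surr = surr)
}
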