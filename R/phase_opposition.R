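# The statistical core: intertrial phase clustering (ITPC), the phase
# opposition sum (POS), label-shuffle surrogate testing, grand-average
# aggregation, multiple-comparison correction, cluster latency, the
# median-latency confidence interval, and phase-binned performance.

#' Intertrial phase clustering
#'
#' Norm of the mean unit phase vector across trials: 1 when all phases are
#' identical, near 0 for uniform phases.
#'
#' @param phases Numeric vector of phases (radians), one per trial, or a
#'   matrix trials x cells (e.g. time points); the statistic is computed per
#'   column.
#' @return Scalar (vector input) or numeric vector per column, in \[0, 1\].
#' @export
itpc <- function(phases) {
  check(length(phases) > 0, "empty phase input")
  if (is.matrix(phases)) {
    Mod(colMeans(exp(1i * phases)))
  } else {
    Mod(mean(exp(1i * phases)))
  }
}

#' Phase opposition sum
#'
#' `POS = ITPC_A + ITPC_B - 2 * ITPC_all`. Theoretical range \[0, 2\] under
#' uniform phase sampling: 2 for perfect opposition (all A trials at one
#' angle, all B trials at the opposite angle), 0 when phases are uniform or
#' both groups lock to the same angle. Compare against label-shuffle
#' surrogates ([surrogate_pos()]) in practice.
#'
#' @param phases Vector (or trials x cells matrix) of phases, radians.
#' @param labels Binary vector (0/1) of trial group membership; both groups
#'   must be present.
#' @return POS per column (scalar for vector input).
#' @export
pos <- function(phases, labels) {
  if (!is.matrix(phases)) phases <- matrix(phases, ncol = 1)
  labels <- as.integer(labels)
  check(length(labels) == nrow(phases), "labels must match trials")
  check(any(labels == 1L) && any(labels == 0L),
        "both trial groups must be present")
  a <- itpc(phases[labels == 1L, , drop = FALSE])
  b <- itpc(phases[labels == 0L, , drop = FALSE])
  all_ <- itpc(phases)
  out <- a + b - 2 * all_
  if (length(out) == 1L) as.numeric(out) else out
}

#' Surrogate test of the phase opposition sum
#'
#' Builds a null distribution of POS values by shuffling the outcome labels
#' across trials (group sizes preserved), computes the z score of the
#' observed POS against the surrogate mean and SD, and converts it to an
#' upper-tail p value through the normal cumulative distribution function
#' (POS is a non-negative-effect statistic, hence one-tailed).
#'
#' @inheritParams pos
#' @param n_perm Number of label shuffles (>= 100).
#' @param seed Integer seed for the shuffles.
#' @return Object of class `pos_result`: `pos`, `z`, `p`, `surrogate_mean`,
#'   `surrogate_sd` (each per column) and `n_perm`.
#' @export
surrogate_pos <- function(phases, labels, n_perm = 1000, seed = 1) {
  if (!is.matrix(phases)) phases <- matrix(phases, ncol = 1)
  labels <- as.integer(labels)
  check(n_perm >= 100, "n_perm must be >= 100")
  check(any(labels == 1L) && any(labels == 0L),
        "both trial groups must be present")
  n <- nrow(phases)
  na <- sum(labels == 1L)
  nb <- n - na
  U <- exp(1i * phases)
  tot <- colSums(U)
  itpc_all <- Mod(tot) / n
  obs_a <- colSums(U[labels == 1L, , drop = FALSE])
  obs <- Mod(obs_a) / na + Mod(tot - obs_a) / nb - 2 * itpc_all

  # surrogate sums for group A via one 0/1 selection matrix multiply
  L <- matrix(0, n_perm, n)
  idx <- with_seed(seed, replicate(n_perm, sample.int(n, na)))
  L[cbind(rep(seq_len(n_perm), each = na), as.vector(idx))] <- 1
  re_a <- L %*% Re(U)
  im_a <- L %*% Im(U)
  surr_a <- sqrt(re_a^2 + im_a^2) / na
  surr_b <- sqrt(sweep(re_a, 2, Re(tot), function(a, s) (s - a))^2 +
                 sweep(im_a, 2, Im(tot), function(a, s) (s - a))^2) / nb
  surr <- sweep(surr_a + surr_b, 2, 2 * itpc_all, `-`)
  mu <- colMeans(surr)
  sd_ <- apply(surr, 2, stats::sd)
  check(all(sd_ > 0), "degenerate surrogate distribution (zero variance)")
  z <- (obs - mu) / sd_
  structure(list(pos = obs, z = z,
                 p = stats::pnorm(z, lower.tail = FALSE),
                 surrogate_mean = mu, surrogate_sd = sd_,
                 n_perm = as.integer(n_perm)),
            class = "pos_result")
}

#' Grand-average POS across subjects
#'
#' Sums observed POS values across subjects (inputs are typically already
#' summed across channels), then builds grand surrogates by repeatedly
#' drawing one stored surrogate per subject and summing, from which grand z
#' scores and upper-tail p values are derived per cell.
#'
#' When `n_resample` exceeds the number of stored surrogates per subject,
#' subject-level surrogates are necessarily reused across resamples
#' (sampling with replacement); a message notes this.
#'
#' @param per_subject_obs Matrix subjects x cells of observed POS values
#'   (vector = one subject).
#' @param per_subject_surrogates List (one element per subject) of
#'   `n_perm x cells` surrogate POS matrices.
#' @param n_resample Number of grand surrogates to draw.
#' @param seed Integer seed.
#' @param chunk Resamples per accumulation chunk (memory control).
#' @return `pos_result` with per-cell grand `pos`, `z`, `p`.
#' @export
grand_average_pos <- function(per_subject_obs, per_subject_surrogates,
                              n_resample = 1e5, seed = 1, chunk = 2000) {
  if (!is.matrix(per_subject_obs)) {
    per_subject_obs <- matrix(per_subject_obs, nrow = 1)
  }
  ns <- nrow(per_subject_obs)
  check(length(per_subject_surrogates) == ns,
        "one surrogate matrix per subject required")
  surr <- lapply(per_subject_surrogates, function(s) {
    if (!is.matrix(s)) matrix(s, ncol = ncol(per_subject_obs)) else s
  })
  n_perm <- vapply(surr, nrow, integer(1))
  if (n_resample > min(n_perm)) {
    message("n_resample exceeds stored surrogates per subject; ",
            "subject surrogates are reused across resamples")
  }
  m <- ncol(per_subject_obs)
  obs <- colSums(per_subject_obs)
  s1 <- numeric(m)
  s2 <- numeric(m)
  done <- 0L
  with_seed(seed, while (done < n_resample) {
    nb <- min(chunk, n_resample - done)
    G <- matrix(0, nb, m)
    for (s in seq_len(ns)) {
      G <- G + surr[[s]][sample.int(n_perm[s], nb, replace = TRUE), ,
                         drop = FALSE]
    }
    s1 <- s1 + colSums(G)
    s2 <- s2 + colSums(G^2)
    done <- done + nb
  })
  mu <- s1 / n_resample
  va <- (s2 - n_resample * mu^2) / (n_resample - 1)
  check(all(va > 0), "degenerate surrogate distribution (zero variance)")
  z <- (obs - mu) / sqrt(va)
  structure(list(pos = obs, z = z,
                 p = stats::pnorm(z, lower.tail = FALSE),
                 surrogate_mean = mu, surrogate_sd = sqrt(va),
                 n_perm = as.integer(n_resample)),
            class = "pos_result")
}

#' Multiple-comparison correction mask
#'
#' Bonferroni keeps p values at or below `alpha / m`; `fdr_bh` applies the
#' Benjamini-Hochberg step-up procedure at level `alpha`.
#'
#' @param p Numeric vector of p values in (0, 1\].
#' @param method `"bonferroni"` or `"fdr_bh"`.
#' @param alpha Significance level.
#' @return Logical mask, TRUE where significant after correction.
#' @export
correct_multiple <- function(p, method = c("bonferroni", "fdr_bh"),
                             alpha = 0.05) {
  method <- match.arg(method)
  check(all(p > 0 & p <= 1), "p values must lie in (0, 1]")
  switch(method,
         bonferroni = p <= alpha / length(p),
         fdr_bh = stats::p.adjust(p, method = "BH") <= alpha)
}

#' Mean latency of the largest significant cluster
#'
#' Finds the longest contiguous run of TRUE values in a significance mask
#' over time and returns the mean of its time points. Ties in run length are
#' resolved in favour of the earliest run. Returns `NA` when nothing is
#' significant (the dataset counts as non-significant).
#'
#' @param mask Logical vector over time points.
#' @param times Numeric vector of time points (same length).
#' @return Mean time of the largest cluster, or `NA_real_`.
#' @export
largest_cluster_latency <- function(mask, times) {
  check(length(mask) == length(times), "mask and times must align")
  if (!any(mask)) return(NA_real_)
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values)
  best <- ok[which.max(r$lengths[ok])]  # which.max takes the first maximum
  mean(times[starts[best]:ends[best]])
}

#' Median latency with distribution-free confidence interval
#'
#' Quartile-based 95% CI of the median:
#' `q2 +/- 1.7 * 1.25 * (q3 - q1) / (1.35 * sqrt(N))`,
#' with quartiles by linear interpolation of order statistics
#' (`stats::quantile` type 7).
#'
#' @param latencies Numeric vector (NA entries, from non-significant
#'   datasets, are dropped); at least 2 finite values required.
#' @return Object of class `latency_distribution`: `latencies`, `median`,
#'   `ci_low`, `ci_high`, `q1`, `q2`, `q3`, `n`.
#' @export
median_latency_ci <- function(latencies) {
  x <- latencies[is.finite(latencies)]
  check(length(x) >= 2, "need at least 2 finite latencies")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  half <- 1.7 * 1.25 * (q[3] - q[1]) / (1.35 * sqrt(length(x)))
  structure(list(latencies = x, median = q[2],
                 ci_low = q[2] - half, ci_high = q[2] + half,
                 q1 = q[1], q2 = q[2], q3 = q[3], n = length(x)),
            class = "latency_distribution")
}

#' Phase-binned detection performance with cosine fit
#'
#' Splits trials into `n_bins` phase bins, computes the hit proportion per
#' bin normalized by the subject's mean performance, and fits
#' `a + b * cos(theta - theta0)` by least squares on (cos, sin) predictors.
#' The reported modulation amplitude is `b` as a percentage of the
#' (normalized) mean. Bin centres are fixed; no realignment across subjects.
#'
#' @param phases Phases (radians) at the frequency/time of interest, one per
#'   trial.
#' @param hits Binary outcomes (1 = hit).
#' @param n_bins Number of phase bins (default 11).
#' @return Object of class `phase_bin_curve`: `bin_centers`,
#'   `normalized_hit_ratio`, `counts`, `cosine_amp_percent`,
#'   `cosine_phase0`, `excluded_bins`.
#' @export
phase_binned_performance <- function(phases, hits, n_bins = 11) {
  check(length(phases) == length(hits), "phases and hits must align")
  hits <- as.integer(hits)
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  ph <- ((phases + pi) %% (2 * pi)) - pi
  bin <- findInterval(ph, edges, rightmost.closed = TRUE)
  bin[bin < 1] <- 1L
  bin[bin > n_bins] <- n_bins
  counts <- tabulate(bin, n_bins)
  rate <- vapply(seq_len(n_bins), function(b) {
    if (counts[b] == 0) NA_real_ else mean(hits[bin == b])
  }, numeric(1))
  norm <- rate / mean(hits)
  keep <- which(counts > 0)
  if (length(keep) < n_bins) {
    message(sprintf("%d empty phase bin(s) excluded from cosine fit",
                    n_bins - length(keep)))
  }
  fit <- cosine_fit(centers[keep], norm[keep])
  structure(list(bin_centers = centers, normalized_hit_ratio = norm,
                 counts = counts,
                 cosine_amp_percent = 100 * fit$amp,
                 cosine_phase0 = fit$phase0,
                 excluded_bins = setdiff(seq_len(n_bins), keep)),
            class = "phase_bin_curve")
}

# Least-squares cosine fit y ~ a + b*cos(theta - theta0) via linear
# regression on cos/sin predictors; amplitude b = sqrt(bc^2 + bs^2).
cosine_fit <- function(theta, y) {
  fit <- stats::lm(y ~ cos(theta) + sin(theta))
  bc <- stats::coef(fit)[2]
  bs <- stats::coef(fit)[3]
  list(amp = sqrt(bc^2 + bs^2), phase0 = atan2(bs, bc),
       intercept = stats::coef(fit)[1])
}
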