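test_that("itpc endpoints", {
  expect_equal(itpc(rep(1.3, 50)), 1)
  n <- 64
  grid <- seq(0, 2 * pi, length.out = n + 1)[1:n] # roots of unity
  expect_lt(itpc(grid), 1e-12)
  m <- cbind(rep(0, 10), rep(c(0, pi), 5))
  expect_equal(itpc(m), c(1, 0))
  expect_error(itpc(numeric(0)), "empty")
})

test_that("pos endpoints and input checks", {
  labels <- rep(c(1, 0), each = 10)
  expect_equal(pos(c(rep(0, 10), rep(pi, 10)), labels), 2)
  expect_equal(pos(rep(0.7, 20), labels), 0)
  expect_error(pos(rep(0, 5), rep(1, 5)), "both trial groups")
  expect_error(pos(rep(0, 5), rep(1, 4)), "match trials")
})

test_that("surrogate_pos is seeded-deterministic and detects opposition", {
  set.seed(42)
  n <- 200
  labels <- rep(c(1L, 0L), each = n / 2)
  ph <- c(rnorm(n / 2, 0, 0.4), rnorm(n / 2, pi, 0.4))
  r1 <- surrogate_pos(ph, labels, n_perm = 500, seed = 5)
  r2 <- surrogate_pos(ph, labels, n_perm = 500, seed = 5)
  expect_identical(r1, r2)
  expect_lt(r1$p, 1e-8)
  expect_gt(r1$z, 6)
  expect_error(surrogate_pos(ph, labels, n_perm = 50), ">= 100")
})

test_that("surrogate_pos z is approximately standard normal under the null", {
  set.seed(99)
  n <- 300
  m <- 400
  ph <- matrix(runif(n * m, -pi, pi), n, m)
  labels <- rep(c(1L, 0L), each = n / 2)
  r <- surrogate_pos(ph, labels, n_perm = 400, seed = 6)
  expect_lt(abs(mean(r$z)), 0.15)
  expect_lt(abs(stats::sd(r$z) - 1), 0.15)
  expect_true(all(r$p > 0 & r$p <= 1))
})

test_that("grand_average_pos matches a direct aggregation oracle", {
  set.seed(7)
  ns <- 3
  m <- 5
  obs <- matrix(rnorm(ns * m, 2, 0.1), ns, m)
  surr <- lapply(1:ns, function(s) matrix(rnorm(500 * m), 500, m))
  expect_message(
    g <- grand_average_pos(obs, surr, n_resample = 2000, seed = 3),
    "reused|reuse")
  # oracle: same resampling performed directly
  direct <- phaselat:::with_seed(3, {
    G <- matrix(0, 2000, m)
    for (s in 1:ns) {
      G <- G + surr[[s]][sample.int(500, 2000, replace = TRUE), ]
    }
    G
  })
  expect_equal(g$pos, colSums(obs))
  expect_equal(g$surrogate_mean, colMeans(direct), tolerance = 1e-10)
  expect_equal(g$surrogate_sd, apply(direct, 2, stats::sd),
               tolerance = 1e-10)
  expect_equal(g$z, (colSums(obs) - colMeans(direct)) /
                 apply(direct, 2, stats::sd), tolerance = 1e-10)
})

test_that("correct_multiple agrees with brute-force oracles", {
  set.seed(11)
  for (k in 1:5) {
    p <- runif(200)^2
    expect_identical(correct_multiple(p, "bonferroni", 0.05), p <= 0.05 / 200)
    expect_identical(correct_multiple(p, "fdr_bh", 0.05),
                     bh_bruteforce(p, 0.05))
  }
  expect_error(correct_multiple(c(0.5, 0)), "lie in")
  expect_error(correct_multiple(c(0.5, 1.2)), "lie in")
})

test_that("largest_cluster_latency handles clusters, ties and edges", {
  tms <- seq(0, 1, by = 0.1)
  expect_true(is.na(largest_cluster_latency(rep(FALSE, 11), tms)))
  m1 <- c(FALSE, TRUE, TRUE, TRUE, rep(FALSE, 7))
  expect_equal(largest_cluster_latency(m1, tms), 0.2)
  # tie: two 2-clusters -> earliest wins
  m2 <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE,
          FALSE)
  expect_equal(largest_cluster_latency(m2, tms), 0.05)
  # cluster reaching the last sample
  m3 <- c(rep(FALSE, 8), TRUE, TRUE, TRUE)
  expect_equal(largest_cluster_latency(m3, tms), 0.9)
  expect_error(largest_cluster_latency(c(TRUE, FALSE), tms), "align")
})

test_that("median_latency_ci implements the quartile CI formula", {
  x <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, NA)
  d <- median_latency_ci(x)
  q <- stats::quantile(x[1:8], c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  half <- 1.7 * 1.25 * (q[3] - q[1]) / (1.35 * sqrt(8))
  expect_equal(d$median, q[2])
  expect_equal(d$ci_low, q[2] - half)
  expect_equal(d$ci_high, q[2] + half)
  expect_equal(d$n, 8L)
  expect_error(median_latency_ci(c(1, NA)), "at least 2")
})

test_that("phase-binned performance recovers an injected cosine modulation", {
  set.seed(21)
  n <- 60000
  ph <- runif(n, -pi, pi)
  hits <- rbinom(n, 1, 0.5 * (1 + 0.4 * cos(ph)))
  curve <- phase_binned_performance(ph, hits)
  expect_length(curve$bin_centers, 11)
  expect_equal(sum(curve$counts), n)
  expect_lt(abs(curve$cosine_amp_percent - 40), 6)
  expect_lt(abs(curve$cosine_phase0), 0.25)
  expect_length(curve$excluded_bins, 0)
})
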