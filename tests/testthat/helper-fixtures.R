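# Shared fixtures, built lazily once per test run.

# Small synthetic-observer cohort reused across the white-noise tests.
tiny_cohort <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      val <<- suppressMessages(
        make_observer_cohort(n_subjects = 3, n_sequences = 10,
                             n_channels = 2, seed = 303))
    }
    val
  }
})

# Brute-force Benjamini-Hochberg step-up mask, used as an oracle against
# correct_multiple().
bh_bruteforce <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ok <- p[o] <= alpha * seq_len(m) / m
  k <- if (any(ok)) max(which(ok)) else 0L
  mask <- logical(m)
  if (k > 0) mask[o[seq_len(k)]] <- TRUE
  mask
}
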