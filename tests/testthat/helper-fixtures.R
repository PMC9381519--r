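# shared fixtures, all generated in code

# a clean six-marker profile in the given decision region
fixture_profile <- function(cd34, cd117, cd13, cd33, mpo, hladr) {
  list(CD34 = cd34, CD117 = cd117, CD13 = cd13, CD33 = cd33,
       MPO = mpo, "HLA-DR" = hladr)
}

# small deterministic event matrix with marker-named channels
fixture_events <- function(values, specimen_id = "fx") {
  # values: named list marker -> numeric vector (equal lengths)
  m <- do.call(cbind, values)
  colnames(m) <- names(values)
  event_matrix(m, specimen_id = specimen_id)
}

# tiny cohort config for fast tests
fixture_config <- function(n = 300, seed = 1, jitter = 0.3, ...) {
  cohort_config(n_patients = n, jitter_sd = jitter, seed = seed, ...)
}

# enumerate all 2x2 tables with the margins of `t`, return two-sided p by
# summing point probabilities <= observed (independent enumeration oracle,
# hypergeometric mass computed from factorials, not dhyper)
enumerate_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  lo <- max(0, r1 - c2); hi <- min(r1, c1)
  logp <- function(x) {
    lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)
  }
  probs <- exp(vapply(lo:hi, logp, numeric(1)))
  p_obs <- exp(logp(a))
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
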