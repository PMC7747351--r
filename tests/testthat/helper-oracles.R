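# Independent brute-force oracles. These deliberately use naive loops and
# never call the vectorized package code paths they are used to check.

oracle_jaccard <- function(b) {
  b <- b > 0
  n <- nrow(b)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      p <- sum(b[i, ] & b[j, ])
      q <- sum(b[i, ] & !b[j, ])
      r <- sum(!b[i, ] & b[j, ])
      out[i, j] <- if (p + q + r > 0) p / (p + q + r) else 0
    }
  }
  out
}

oracle_cosine <- function(p) {
  n <- nrow(p)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      ni <- sqrt(sum(p[i, ]^2))
      nj <- sqrt(sum(p[j, ]^2))
      out[i, j] <- if (ni > 0 && nj > 0) sum(p[i, ] * p[j, ]) / (ni * nj)
        else 0
    }
  }
  out
}

oracle_gip <- function(profiles, omega) {
  n <- nrow(profiles)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      out[i, j] <- exp(-omega * sum((profiles[i, ] - profiles[j, ])^2))
    }
  }
  out
}

# Elementwise NCP from the formulas, independent of the package's
# vectorized and scalar implementations.
oracle_ncp <- function(a, sd_v, sm_v) {
  nd <- nrow(a)
  nm <- ncol(a)
  out <- matrix(0, nd, nm)
  for (i in seq_len(nd)) {
    for (j in seq_len(nm)) {
      nai <- sqrt(sum(a[i, ]^2))
      naj <- sqrt(sum(a[, j]^2))
      msp <- if (nai > 0) sum(a[i, ] * sm_v[, j]) / nai else 0
      dsp <- if (naj > 0) sum(sd_v[i, ] * a[, j]) / naj else 0
      out[i, j] <- (dsp + msp) /
        (sqrt(sum(sd_v[i, ]^2)) + sqrt(sum(sm_v[, j]^2)))
    }
  }
  out
}

# Exhaustive Mann-Whitney pair counting with midrank ties.
oracle_auc <- function(tests, cands) {
  total <- 0
  for (t in tests) {
    for (c in cands) {
      total <- total + (t > c) + 0.5 * (t == c)
    }
  }
  total / (length(tests) * length(cands))
}
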