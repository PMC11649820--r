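# Independent oracles, deliberately structured differently from the
# production code paths they check.

# Brute-force staging of one series by explicit window enumeration.
# times in days (numeric), values in umol/L. Returns integer stages.
oracle_stage_series <- function(days, values, high_c1_on = TRUE) {
  m <- length(days)
  out <- integer(m)
  for (i in seq_len(m)) {
    c1 <- values[i]
    rv1s <- rv2s <- m48s <- numeric(0)
    for (j in seq_len(m)) {
      gap <- days[i] - days[j]
      if (gap <= 0) next
      if (gap < 7) rv1s <- c(rv1s, values[j])
      if (gap >= 7 && gap <= 365) rv2s <- c(rv2s, values[j])
      if (gap < 2) m48s <- c(m48s, values[j])
    }
    ratios <- numeric(0)
    if (length(rv1s)) ratios <- c(ratios, c1 / min(rv1s))
    if (length(rv2s)) ratios <- c(ratios, c1 / median(rv2s))
    s <- 0L
    if (length(ratios)) {
      r <- max(ratios)
      if (r >= 3) s <- 3L
      else if (r >= 1.5 && c1 >= 354 && high_c1_on) s <- 3L
      else if (r >= 2) s <- 2L
      else if (r >= 1.5) s <- 1L
    }
    if (s == 0L && length(m48s) && c1 - min(m48s) > 26) s <- 1L
    out[i] <- s
  }
  out
}

# Direct per-subject summation of the weighted Gwet coefficient from raw
# stage pairs (no confusion-matrix shortcut).
oracle_gwet <- function(a, b, w) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  q <- nrow(w)
  pa <- 0
  pik <- numeric(q)
  for (s in seq_len(n)) {
    pa <- pa + w[a[s] + 1, b[s] + 1] / n
    for (k in seq_len(q) - 1) {
      pik[k + 1] <- pik[k + 1] + ((a[s] == k) + (b[s] == k)) / (2 * n)
    }
  }
  pe <- sum(w) / (q * (q - 1)) * sum(pik * (1 - pik))
  (pa - pe) / (1 - pe)
}

# expand a confusion matrix back into stage-pair vectors
matrix_to_pairs <- function(m) {
  q <- nrow(m)
  a <- b <- integer(0)
  for (k in seq_len(q)) for (l in seq_len(q)) {
    a <- c(a, rep(k - 1L, m[k, l]))
    b <- c(b, rep(l - 1L, m[k, l]))
  }
  list(local = a, central = b)
}
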