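# Independent brute-force oracles used across the test files. These are
# deliberately written as plain double loops over candidate change
# points and grid levels, sharing no code with the package internals.

oracle_npcps <- function(normal, cancer, grid_size = 100) {
  n1 <- length(normal)
  z <- c(normal, cancer)
  n <- length(z)
  sorted <- sort(normal)
  best_d <- 0
  best_r <- 1L
  have <- FALSE
  for (r in 1:(n - 2)) {
    tail <- z[(r + 1):n]
    m <- length(tail)
    d_pos <- -Inf
    d_neg <- -Inf
    for (j in 1:grid_size) {
      y <- j / (grid_size + 1)
      q <- sorted[ceiling(y * n1)]
      f_le <- sum(tail <= q) / m
      f_lt <- sum(tail < q) / m
      if (f_le - y > d_pos) d_pos <- f_le - y
      if (y - f_lt > d_neg) d_neg <- y - f_lt
    }
    delta <- if (d_pos >= d_neg) d_pos else -d_neg
    d <- sqrt(m) * delta
    if (!have || abs(d) > abs(best_d)) {
      best_d <- d
      best_r <- r
      have <- TRUE
    }
  }
  list(D = best_d, r = best_r)
}

# Linear-interpolation percentile computed from first principles.
oracle_percentile <- function(v, p) {
  s <- sort(v)
  h <- (length(s) - 1) * p / 100 + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# AUC by exhaustive pair counting, ties worth one half.
oracle_auc <- function(null_scores, dge_scores) {
  wins <- 0
  for (d in dge_scores) {
    for (h in null_scores) {
      if (d > h) wins <- wins + 1 else if (d == h) wins <- wins + 0.5
    }
  }
  wins / (length(null_scores) * length(dge_scores))
}

# Likelihood-ratio scan by direct enumeration of every cut.
oracle_lrs <- function(normal, cancer) {
  s <- c(normal, sort(cancer))
  n <- length(s)
  sst <- sum((s - mean(s))^2)
  best <- -Inf
  for (j in 1:(length(cancer) - 1)) {
    top <- s[(n - j + 1):n]
    bg <- s[1:(n - j)]
    ss1 <- sum((top - mean(top))^2) + sum((bg - mean(bg))^2)
    lr <- n * log(max(sst, 1e-8) / max(ss1, 1e-8))
    if (lr > best) best <- lr
  }
  best
}
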