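# Brute-force oracles, kept deliberately independent of the package
# implementations they check: plain textbook formulas and O(n^2) loops.

o_germination_rate <- function(n_new, n_total) 100 * sum(n_new) / n_total

o_germination_potential <- function(n_new, day, gp_day, n_total) {
  total <- 0
  for (i in seq_along(day)) if (day[i] <= gp_day) total <- total + n_new[i]
  100 * total / n_total
}

o_germination_index <- function(n_new, day) {
  gi <- 0
  for (i in seq_along(day)) gi <- gi + n_new[i] / day[i]
  gi
}

o_vigor_index <- function(gi, w) gi * w

o_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

o_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  m <- sum(d) / n
  s <- sqrt(sum((d - m)^2) / (n - 1))
  t <- m / (s / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1))
}

o_welch_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  ma <- mean(a); mb <- mean(b)
  va <- sum((a - ma)^2) / (na - 1); vb <- sum((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# AUC by explicit positive/negative pair counting, ties worth 1/2
o_auc_pairs <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  wins <- 0
  for (p in pos) for (q in neg) {
    wins <- wins + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  wins / (length(pos) * length(neg))
}

# random small germination instance for property tests
rand_obs <- function() {
  k <- sample(3:8, 1)
  nt <- sample(20:60, 1)
  n_new <- numeric(k)
  left <- nt
  for (i in seq_len(k)) {
    n_new[i] <- sample(0:min(left, 15), 1)
    left <- left - n_new[i]
  }
  data.frame(day = seq_len(k), n_new = n_new, n_total = nt)
}
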