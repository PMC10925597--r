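# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# Raw-moment Pearson correlation: r = (N*Sxy - Sx*Sy) / sqrt([..][..]).
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  num / den
}

# Brute-force plug-in mutual information (nats) over a discrete joint.
oracle_mi <- function(x, y) {
  tab <- table(x, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  total <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    if (p[i, j] > 0) {
      total <- total + unname(p[i, j] * log(p[i, j] / (px[i] * py[j])))
    }
  }
  total
}

# O(n^2) concordant/discordant pair count AUC with half-credit for ties.
oracle_auc <- function(y, s) {
  pos <- which(y == 1); neg <- which(y == 0)
  total <- 0
  for (i in pos) for (j in neg) {
    total <- total + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
  }
  total / (length(pos) * length(neg))
}

# Single-pass omega evaluation (the formula spelled out).
oracle_omega <- function(uids, p_c, p_n) {
  total <- 0
  for (i in seq_along(uids)) {
    total <- total + (uids[i] / sum(uids)) * log(p_c[i] / p_n[i])
  }
  total
}
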