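# Independent brute-force oracles for the permutation statistics. These
# recompute each statistic from its definition, never through the package
# or vegan, and enumerate label arrangements exhaustively on small inputs.

oracle_adonis_F <- function(d, labels) {
  D <- as.matrix(d)
  n <- nrow(D)
  a <- length(unique(labels))
  ss_total <- sum(D[upper.tri(D)]^2) / n
  ss_within <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    if (length(idx) > 1) {
      sub <- D[idx, idx]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]^2) / length(idx)
    }
  }
  ss_between <- ss_total - ss_within
  (ss_between / (a - 1)) / (ss_within / (n - a))
}

oracle_mrpp_delta <- function(d, labels) {
  D <- as.matrix(d)
  n <- nrow(D)
  delta <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    if (length(idx) > 1) {
      sub <- D[idx, idx]
      delta <- delta + length(idx) / n * mean(sub[upper.tri(sub)])
    }
  }
  delta
}

oracle_anosim_R <- function(d, labels) {
  D <- as.matrix(d)
  n <- nrow(D)
  ut <- upper.tri(D)
  r <- rank(D[ut])
  same <- outer(labels, labels, "==")[ut]
  M <- n * (n - 1) / 2
  (mean(r[!same]) - mean(r[same])) / (M / 2)
}

# all distinct two-group assignments of n samples into groups of size k
# and n - k (as a list of label vectors)
enumerate_two_groups <- function(n, k) {
  apply(utils::combn(n, k), 2, function(idx) {
    lab <- rep("b", n)
    lab[idx] <- "a"
    lab
  }, simplify = FALSE)
}
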