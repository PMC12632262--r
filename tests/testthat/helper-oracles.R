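# Independent brute-force oracles and small fixture builders shared by the
# test files. The oracles deliberately avoid the package's code paths.

AA <- amino_acids()

# MI in bits by explicit double sum over the observed letter-pair table,
# with pairwise deletion of gapped rows.
brute_mi <- function(x, y) {
  keep <- x != "-" & y != "-"
  x <- x[keep]
  y <- y[keep]
  tab <- table(x, y)
  n <- sum(tab)
  px <- rowSums(tab) / n
  py <- colSums(tab) / n
  mi <- 0
  for (a in rownames(tab)) {
    for (b in colnames(tab)) {
      p <- tab[a, b] / n
      if (p > 0) mi <- mi + p * log2(p / (px[[a]] * py[[b]]))
    }
  }
  unname(mi)
}

# Shannon entropy (bits) of one column over its non-gap residues.
brute_entropy <- function(x) {
  x <- x[x != "-"]
  p <- table(x) / length(x)
  -sum(p * log2(p))
}

# Random residue column, optionally with gaps, over a small sub-alphabet so
# that joint tables are well populated at small n.
random_column <- function(n, alphabet = AA[1:4], gap_prob = 0) {
  x <- sample(alphabet, n, replace = TRUE)
  if (gap_prob > 0) x[runif(n) < gap_prob] <- "-"
  x
}

# Per-node-maximum reimplementation of the best-neighbor rule.
brute_best_neighbor <- function(edges) {
  keep <- logical(nrow(edges))
  for (e in seq_len(nrow(edges))) {
    u <- edges$pos_i[e]
    v <- edges$pos_j[e]
    max_u <- max(edges$score[edges$pos_i == u | edges$pos_j == u])
    max_v <- max(edges$score[edges$pos_i == v | edges$pos_j == v])
    keep[e] <- edges$score[e] >= max_u || edges$score[e] >= max_v
  }
  edges[keep, , drop = FALSE]
}

# Seven-column toy map: landmarks at columns 1, 2, 3, 5, 7.
toy_map <- function() {
  landmark_map_from_columns(c(DD1 = 1, DD2 = 2, D = 3, T = 5, K = 7), 7, "toy")
}

# A receiver row under toy_map() and default rules.
toy_receiver_row <- "DDDATAK"

# 99% binomial acceptance interval for an observed proportion.
binom99 <- function(n, p) qbinom(c(0.005, 0.995), n, p) / n
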