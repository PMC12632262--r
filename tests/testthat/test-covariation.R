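test_that("column MI handles the analytic cases", {
  expect_equal(column_mi(rep("A", 10), rep("A", 10)), 0)
  # perfectly coupled two-letter columns, 50/50 split: exactly 1 bit
  x <- rep(c("A", "C"), each = 10)
  y <- rep(c("G", "W"), each = 10)
  expect_equal(column_mi(x, y), 1.0)
  # rows gapped at either column are dropped pairwise
  xg <- c(x, "-", "A")
  yg <- c(y, "G", "-")
  expect_equal(column_mi(xg, yg), 1.0)
  expect_error(column_mi(c("-", "-", "A"), c("A", "A", "-")),
               "insufficient coverage")
  expect_error(column_mi(c("A", "A"), c("A", "A", "A")), "equal length")
})

test_that("column MI equals the brute-force double sum and obeys the entropy bound", {
  set.seed(101)
  for (i in 1:60) {
    n <- sample(6:20, 1)
    x <- random_column(n, gap_prob = 0.15)
    y <- random_column(n, gap_prob = 0.15)
    if (sum(x != "-" & y != "-") < 2) next
    mi <- column_mi(x, y)
    expect_lt(abs(mi - brute_mi(x, y)), 1e-12)
    expect_gte(mi, -1e-12)
    keep <- x != "-" & y != "-"
    expect_lte(mi, min(brute_entropy(x[keep]), brute_entropy(y[keep])) + 1e-12)
  }
})

test_that("average-product correction matches hand arithmetic on a 4x4 toy", {
  m <- matrix(0, 4, 4)
  m[1, 2] <- m[2, 1] <- 4
  m[1, 3] <- m[3, 1] <- 2
  m[1, 4] <- m[4, 1] <- 2
  m[2, 3] <- m[3, 2] <- 2
  m[2, 4] <- m[4, 2] <- 2
  m[3, 4] <- m[4, 3] <- 0
  # row means: 8/3, 8/3, 4/3, 4/3; overall off-diagonal mean: 2
  corr <- product_correction(m)
  expect_equal(corr[1, 2], 4 - (8 / 3)^2 / 2)
  expect_equal(corr[1, 3], 2 - (8 / 3) * (4 / 3) / 2)
  expect_equal(corr[3, 4], 0 - (4 / 3)^2 / 2)
  expect_equal(corr, t(corr))
  expect_true(all(is.na(diag(corr))))
})

test_that("APC degenerate rules: constant matrices zero out, all-zero stays zero", {
  for (c_val in c(0.1, 1, 3)) {
    for (p in c(3, 5, 8)) {
      m <- matrix(c_val, p, p)
      corr <- product_correction(m)
      expect_lt(max(abs(corr[upper.tri(corr)])), 1e-12)
    }
  }
  z <- product_correction(matrix(0, 5, 5))
  expect_true(all(z[upper.tri(z)] == 0))
})

test_that("global z-scores flag constructed outliers and degenerate spreads", {
  # 46 columns -> 1035 pairs; baseline scores cycle through small values,
  # one pair is extreme by construction
  p <- 46
  m <- matrix(0, p, p)
  vals <- rep(c(0.01, 0.02, 0.03), length.out = p * (p - 1) / 2)
  m[upper.tri(m)] <- vals
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m[1, 2] <- m[2, 1] <- 5
  sig <- mi_significance(m, threshold = 6.5)
  expect_true(sig$significant[1, 2])
  expect_equal(sum(sig$significant[upper.tri(sig$significant)]), 1)
  # all-equal scores: degenerate, warned, nothing significant
  flat <- matrix(0.5, 6, 6)
  expect_warning(sig2 <- mi_significance(flat), "degenerate score distribution")
  expect_false(any(sig2$significant, na.rm = TRUE))
})

test_that("percentile ranks follow the shared-tie convention", {
  # 3 columns -> 3 pairs with distinct scores
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 0.1
  m[1, 3] <- m[3, 1] <- 0.2
  m[2, 3] <- m[3, 2] <- 0.3
  pct <- rank_pairs(m)
  expect_equal(pct[1, 2], 100 * 1 / 3)
  expect_equal(pct[1, 3], 100 * 2 / 3)
  expect_equal(pct[2, 3], 100)
  # all tied: every pair shares the mean rank
  tied <- rank_pairs(matrix(1, 4, 4))
  ut <- tied[upper.tri(tied)]
  expect_equal(ut, rep(ut[1], length(ut)))
  # top-k selection uses ceiling and keeps boundary ties
  scores <- seq_len(4950)
  expect_length(psrcov:::top_fraction_idx(scores, 0.01), 50)
  with_tie <- c(rep(100, 3), seq_len(97))
  expect_length(psrcov:::top_fraction_idx(with_tie, 0.01), 3)
})

test_that("covariation analysis drops high-gap columns and records metadata", {
  set.seed(7)
  spec <- synthetic_spec(150, 12, gap_rate = c(rep(0, 11), 0.8), seed = 3)
  aln <- generate_alignment(spec)$alignment
  cov <- covariation_analysis(aln, max_gap_fraction = 0.5)
  expect_equal(length(cov$ref_numbers), 11)  # gappy column excluded
  expect_false(12 %in% cov$ref_numbers)
  expect_equal(cov$unit, "bits")
  expect_equal(cov$raw_mi, t(cov$raw_mi))
  expect_true(all(cov$raw_mi[upper.tri(cov$raw_mi)] >= 0))
  # percentile ranks are a monotone transform of corrected MI
  pt <- pair_table(cov)
  ord <- order(pt$corrected_mi)
  expect_true(all(diff(pt$percentile[ord]) >= 0))
})

test_that("rank shifts are antisymmetric and empty for identical inputs", {
  set.seed(11)
  spec_a <- synthetic_spec(250, 20,
                           coupled = list(coupled_block(c(2, 9), 0.9)),
                           group_label = "A", seed = 5)
  spec_b <- synthetic_spec(250, 20,
                           coupled = list(coupled_block(c(4, 15), 0.9)),
                           group_label = "B", seed = 6)
  cov_a <- covariation_analysis(generate_alignment(spec_a)$alignment)
  cov_b <- covariation_analysis(generate_alignment(spec_b)$alignment)

  rs_ab <- rank_shift(cov_a, cov_b)
  rs_ba <- rank_shift(cov_b, cov_a)
  expect_equal(rs_ab$pairs$shift, -rs_ba$pairs$shift)
  # every reported pair is significant in at least one group
  expect_true(all(rs_ab$pairs$significant_in %in% c("receiver", "psr", "both")))
  # the A-only pair shifts positive with A as receiver, negative when swapped
  a_pair <- rs_ab$pairs$pos_i == 2 & rs_ab$pairs$pos_j == 9
  expect_true(any(a_pair))
  expect_gt(rs_ab$pairs$shift[a_pair], 0)
  expect_lt(rs_ba$pairs$shift[a_pair], 0)

  # identical inputs: all shifts zero, no pair selected as a change
  rs_same <- rank_shift(cov_a, cov_a)
  expect_true(all(rs_same$pairs$shift == 0))
  expect_equal(nrow(rs_same$top), 0)

  cov_small <- covariation_analysis(
    generate_alignment(synthetic_spec(100, 8, seed = 9))$alignment)
  expect_error(rank_shift(cov_a, cov_small), "alignments not comparable")
})
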