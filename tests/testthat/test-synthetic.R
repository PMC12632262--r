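test_that("generation is a pure function of the spec and seed", {
  spec <- synthetic_spec(40, 15,
                         landmarks = list(D = landmark_site(5, "D", 0.7)),
                         coupled = list(coupled_block(c(2, 9), 0.8)),
                         gap_rate = 0.05, seed = 77)
  g1 <- generate_alignment(spec)
  g2 <- generate_alignment(spec)
  expect_identical(g1$alignment$residues, g2$alignment$residues)
  expect_identical(g1$truth, g2$truth)
  spec2 <- synthetic_spec(40, 15,
                          landmarks = list(D = landmark_site(5, "D", 0.7)),
                          coupled = list(coupled_block(c(2, 9), 0.8)),
                          gap_rate = 0.05, seed = 78)
  expect_false(identical(generate_alignment(spec2)$alignment$residues,
                         g1$alignment$residues))
  # the generator must not disturb the caller's RNG stream
  set.seed(1)
  before <- runif(1)
  set.seed(1)
  invisible(generate_alignment(spec))
  expect_identical(runif(1), before)
})

full_landmarks <- function(probs, fallback_d = NULL) {
  list(DD1 = landmark_site(3, c("D", "E"), probs[["DD1"]]),
       DD2 = landmark_site(4, c("D", "E"), probs[["DD2"]]),
       D = landmark_site(8, "D", probs[["D"]], fallback = fallback_d),
       T = landmark_site(12, c("S", "T"), probs[["T"]]),
       K = landmark_site(15, "K", probs[["K"]]))
}

test_that("landmark conservation closes the loop with the classifier", {
  # full conservation -> every row classifies as receiver
  all_on <- synthetic_spec(
    60, 18, landmarks = full_landmarks(
      c(DD1 = 1, DD2 = 1, D = 1, T = 1, K = 1)), seed = 4)
  g <- generate_alignment(all_on)
  part <- partition_set(g$alignment, g$map)
  expect_equal(n_sequences(part$receivers), 60)

  # D never conserved, fallback pinned to Glu -> every row is an ALR
  alr_spec <- synthetic_spec(
    60, 18, landmarks = full_landmarks(
      c(DD1 = 1, DD2 = 1, D = 0, T = 1, K = 1), fallback_d = c(E = 1)),
    seed = 5)
  ga <- generate_alignment(alr_spec)
  parta <- partition_set(ga$alignment, ga$map)
  expect_equal(n_sequences(parta$psrs), 60)
  expect_true(all(parta$calls$is_ALR))
  # and the generator's own truth record agrees with the classifier
  expect_equal(unname(parta$calls$call), unname(ga$truth$call))
})

test_that("empirical composition converges to the background distribution", {
  bias <- list("2" = c(A = 0.45, G = 0.29), "5" = c(W = 0.02))
  spec <- synthetic_spec(5000, 6, background = make_background(6, bias),
                         seed = 13)
  aln <- generate_alignment(spec)$alignment
  freq_of <- function(col, letter) mean(aln$residues[, col] == letter)
  for (case in list(c(2, "A", 0.45), c(2, "G", 0.29), c(5, "W", 0.02))) {
    ci <- binom99(5000, as.numeric(case[3]))
    got <- freq_of(as.integer(case[1]), case[2])
    expect_gte(got, ci[1])
    expect_lte(got, ci[2])
  }
})

test_that("planted MI is monotone in coupling strength and matches its closed form", {
  # Background restricted to the two combo letters keeps the marginals at
  # 50/50 for every coupling strength, so the mixture MI has the closed form
  #   MI(t) = 2 p_s log2(4 p_s) + 2 p_d log2(4 p_d),
  #   p_s = t/2 + (1-t)/4, p_d = (1-t)/4,
  # which increases strictly from 0 (t = 0) to 1 bit (t = 1).
  bg <- make_background(10, list("3" = c(W = 0.5, C = 0.5),
                                 "8" = c(W = 0.5, C = 0.5)))
  mi_at <- function(strength, seed) {
    spec <- synthetic_spec(2000, 10, background = bg,
                           coupled = list(coupled_block(c(3, 8), strength)),
                           seed = seed)
    aln <- generate_alignment(spec)$alignment
    column_mi(aln$residues[, 3], aln$residues[, 8])
  }
  closed_form <- function(t) {
    p_s <- t / 2 + (1 - t) / 4
    p_d <- (1 - t) / 4
    2 * p_s * log2(4 * p_s) + 2 * p_d * log2(4 * p_d)
  }
  strengths <- c(0.3, 0.6, 0.9)
  mis <- vapply(strengths, mi_at, numeric(1), seed = 91)
  expect_true(all(diff(mis) > 0))
  expect_equal(mis, closed_form(strengths), tolerance = 0.15)
})

test_that("spec validation rejects inconsistent inputs", {
  expect_error(coupled_block(c(3, 3), 0.5), "distinct")
  expect_error(coupled_block(c(3, 7), 1.5), "\\[0,1\\]")
  expect_error(coupled_block(c(3, 7), 0.5, combos = list(c("A", "B"), c("C", "D"))),
               "amino acids")
  expect_error(landmark_site(2, "D", 0.5, fallback = c(D = 1)),
               "outside the conserved class")
  expect_error(synthetic_spec(10, 8,
                              landmarks = list(D = landmark_site(4, "D", 1)),
                              coupled = list(coupled_block(c(4, 6), 0.5))),
               "landmark columns")
  expect_error(synthetic_spec(10, 8, gap_rate = 2), "\\[0,1\\]")
  a <- synthetic_spec(10, 8, seed = 1)
  b <- synthetic_spec(10, 9, seed = 1)
  expect_error(make_two_group_fixture(a, b), "mismatched columns")
})

test_that("two-group fixtures share the column map and record group truths", {
  specs <- psr_study_specs(n_receiver = 150, n_psr = 150, seed = 55)
  fix <- make_two_group_fixture(specs$receiver, specs$psr)
  expect_equal(fix$receiver$n_columns, fix$psr$n_columns)
  expect_equal(unname(fix$map$landmark_columns),
               c(12, 13, 57, 87, 109))
  expect_equal(length(fix$truth_receiver$coupled_rows), 4)
  # planted receiver conservation is total; PsR group is mostly PsR
  expect_true(all(fix$truth_receiver$call == "receiver"))
  expect_gt(mean(fix$truth_psr$call == "pseudo_receiver"), 0.85)
})
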