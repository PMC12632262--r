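test_that("best-neighbor filter keeps each node's maximal edges", {
  # star: the center's best edge survives via the center, every other edge
  # survives as its leaf's only (hence best) edge -> all retained
  star <- data.frame(pos_i = 1, pos_j = 2:5, score = c(4, 3, 2, 1))
  expect_equal(nrow(best_neighbor_filter(star)), 4)

  # path a-b-c with score(ab) > score(bc): bc survives as c's best
  path <- data.frame(pos_i = c(1, 2), pos_j = c(2, 3), score = c(2, 1))
  expect_equal(nrow(best_neighbor_filter(path)), 2)

  # random scored graphs match the brute-force per-node-max oracle
  set.seed(19)
  for (i in 1:20) {
    all_pairs <- t(combn(8, 2))
    take <- sample(nrow(all_pairs), sample(6:16, 1))
    edges <- data.frame(pos_i = all_pairs[take, 1], pos_j = all_pairs[take, 2],
                        score = round(runif(length(take)), 3))
    expect_equal(best_neighbor_filter(edges), brute_best_neighbor(edges),
                 ignore_attr = TRUE)
  }
})

# covariation on an alignment with planted blocks; cols chosen clear of ends
planted_cov <- function(blocks, n = 400, p = 30, seed = 23) {
  spec <- synthetic_spec(n, p, coupled = blocks, group_label = "net",
                         seed = seed)
  covariation_analysis(generate_alignment(spec)$alignment)
}

test_that("a coupled triangle forms one cluster; lone pairs fall below min size", {
  cov3 <- planted_cov(list(coupled_block(c(4, 11, 19), 0.9)))
  net3 <- build_networks(cov3, core_pct = 1, extended_pct = 1)  # all significant pairs are core
  expect_length(net3$clusters, 1)
  expect_equal(net3$clusters[[1]]$members, c(4, 11, 19))
  expect_gte(net3$clusters[[1]]$n_core_members, net3$min_cluster_size)

  # two disjoint coupled pairs: 2-node components are discarded
  cov2 <- planted_cov(list(coupled_block(c(4, 11), 0.9),
                           coupled_block(c(19, 26), 0.9)))
  net2 <- build_networks(cov2, core_pct = 1, extended_pct = 1)
  expect_length(net2$clusters, 0)
  expect_gte(nrow(net2$core_edges), 2)  # edges exist, clusters do not
})

test_that("network tiers partition the significant pairs and respect percentiles", {
  cov <- planted_cov(list(coupled_block(c(4, 11, 19), 0.9),
                          coupled_block(c(7, 24), 0.7)))
  net <- build_networks(cov, core_pct = 0.5, extended_pct = 1)
  core_keys <- paste(net$core_edges$pos_i, net$core_edges$pos_j)
  ext_keys <- paste(net$extended_edges$pos_i, net$extended_edges$pos_j)
  expect_length(intersect(core_keys, ext_keys), 0)
  sig_keys <- with(subset(pair_table(cov), significant), paste(pos_i, pos_j))
  expect_true(all(c(core_keys, ext_keys) %in% sig_keys))
  if (nrow(net$core_edges) && nrow(net$extended_edges)) {
    expect_gte(min(net$core_edges$score), max(net$extended_edges$score))
  }
})

test_that("raising core_pct never removes previously clustered nodes", {
  cov <- planted_cov(list(coupled_block(c(4, 11, 19), 0.9),
                          coupled_block(c(7, 16, 24, 28), 0.85)))
  nodes_at <- function(pct) {
    net <- build_networks(cov, core_pct = pct, extended_pct = 1)
    sort(unique(unlist(lapply(net$clusters, `[[`, "members"))))
  }
  small <- nodes_at(0.3)
  larger <- nodes_at(0.7)
  full <- nodes_at(1)
  expect_true(all(small %in% larger))
  expect_true(all(larger %in% full))
})

test_that("cluster membership ignores edge insertion order", {
  cov <- planted_cov(list(coupled_block(c(4, 11, 19), 0.9)))
  net1 <- build_networks(cov, core_pct = 1, extended_pct = 1)
  # permute the underlying column order and re-analyze: same membership
  cov_rev <- cov
  perm <- rev(seq_along(cov$ref_numbers))
  for (f in c("raw_mi", "corrected_mi", "zscores", "percentile_rank", "significant")) {
    cov_rev[[f]] <- cov[[f]][perm, perm]
  }
  cov_rev$ref_numbers <- cov$ref_numbers[perm]
  net2 <- build_networks(cov_rev, core_pct = 1, extended_pct = 1)
  expect_equal(lapply(net1$clusters, `[[`, "members"),
               lapply(net2$clusters, `[[`, "members"))
})

test_that("hub scores sum incident significant edges for both endpoints", {
  # a single strong pair: both endpoints carry the edge's score, degree 1
  cov1 <- planted_cov(list(coupled_block(c(4, 11), 0.9)))
  hub1 <- hub_report(cov1)
  pt <- subset(pair_table(cov1), significant)
  edge_score <- pt$corrected_mi[pt$pos_i == 4 & pt$pos_j == 11]
  expect_equal(hub1$scores$cumulative[hub1$scores$position == 4], edge_score)
  expect_equal(hub1$scores$cumulative[hub1$scores$position == 11], edge_score)
  expect_true(all(hub1$scores$degree[hub1$scores$position %in% c(4, 11)] == 1))

  # total cumulative score is twice the sum over significant edges
  cov <- planted_cov(list(coupled_block(c(4, 11, 19), 0.9),
                          coupled_block(c(7, 24), 0.8)))
  hub <- hub_report(cov)
  sig <- subset(pair_table(cov), significant)
  expect_equal(sum(hub$scores$cumulative), 2 * sum(sig$corrected_mi))

  # a planted hub touching several partners ranks first
  # 10 near-equal planted pairs need a wide background so the global z
  # does not saturate below threshold
  covh <- planted_cov(list(coupled_block(c(4, 9, 14, 19, 23), 0.9)), p = 45)
  hubh <- hub_report(covh, k = 3)
  expect_true(hubh$top$position[1] %in% c(4, 9, 14, 19, 23))
  expect_equal(nrow(hubh$top), 3)

  # no significant edges -> empty report
  cov0 <- covariation_analysis(
    generate_alignment(synthetic_spec(120, 10, seed = 41))$alignment)
  expect_equal(nrow(hub_report(cov0)$scores), 0)
})
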