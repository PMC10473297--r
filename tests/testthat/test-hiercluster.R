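test_that("modularity_matrix recentres by the upper-triangle mean", {
  C <- matrix(c(1, 0.6, 0.6, 1), 2, 2)
  B <- modularity_matrix(C)
  expect_equal(attr(B, "p_exp"), 0.6)
  expect_equal(B[1, 2], 0)
  # 3x3 with off-diagonals {0.9, 0.1, 0.2}: P_exp = 0.4
  C <- diag(3); C[1, 2] <- C[2, 1] <- 0.9
  C[1, 3] <- C[3, 1] <- 0.1; C[2, 3] <- C[3, 2] <- 0.2
  B <- modularity_matrix(C)
  expect_equal(attr(B, "p_exp"), 0.4)
  expect_equal(B[1, 2], 0.5)
  expect_equal(B[1, 3], -0.3)
  expect_equal(B[2, 3], -0.2)
  expect_equal(diag(B), rep(0, 3))
  # zero-sum invariant on random matrices
  set.seed(21)
  for (i in 1:10) {
    n <- sample(3:12, 1)
    M <- matrix(rnorm(n^2), n, n); M <- (M + t(M)) / 2; diag(M) <- 1
    B <- modularity_matrix(M)
    expect_equal(sum(B[upper.tri(B)]), 0, tolerance = 1e-10)
  }
})

test_that("louvain recovers planted blocks; all-negative gives singletons", {
  pb <- planted_B(2, 6, noise = 0.05, seed = 2)
  lab <- louvain_partition(pb$B, seed = 7)
  expect_equal(nmi_oracle(lab, pb$labels), 1)
  Bneg <- matrix(-0.3, 6, 6); diag(Bneg) <- 0
  expect_equal(louvain_partition(Bneg, 1), 1:6)
})

test_that("consensus matches the exhaustive optimum on small instances", {
  set.seed(22)
  hits <- 0
  for (i in 1:40) {
    n <- sample(5:7, 1)
    M <- random_small_B(n, seed = 300 + i)
    qstar <- oracle_max_modularity(M)
    lab <- consensus_partition(M, n_runs = 20, seed = i)
    q <- partition_modularity(M, lab)
    expect_lte(q, qstar + 1e-9)
    if (abs(q - qstar) < 1e-9) hits <- hits + 1
  }
  expect_gte(hits / 40, 0.95)
  # soundness on unstructured matrices: never exceeds the true optimum
  for (i in 1:5) {
    n <- 6
    M <- matrix(rnorm(n^2, sd = 0.5), n, n); M <- (M + t(M)) / 2
    diag(M) <- 0
    q <- partition_modularity(M, consensus_partition(M, n_runs = 20,
                                                     seed = i))
    expect_lte(q, oracle_max_modularity(M) + 1e-9)
  }
})

test_that("community_contribution conventions and additivity", {
  B <- matrix(0, 3, 3); B[1, 2] <- B[2, 1] <- 0.5
  expect_equal(community_contribution(B, c(1, 1, 2), 1), 1.0)
  expect_equal(community_contribution(B, c(1, 2, 3), 3), 0)
  set.seed(23)
  M <- matrix(rnorm(64), 8, 8); M <- (M + t(M)) / 2; diag(M) <- 0
  for (i in 1:5) {
    lab <- sample(1:3, 8, replace = TRUE)
    expect_equal(partition_modularity(M, lab),
                 sum(vapply(unique(lab), function(c)
                   community_contribution(M, lab, c), numeric(1))))
  }
})

test_that("consensus recovers planted labels and is relabel-invariant", {
  pb <- planted_B(3, 10, within = 0.5, between = -0.2, noise = 0.1, seed = 3)
  lab <- consensus_partition(pb$B, n_runs = 50, seed = 11)
  expect_equal(nmi_oracle(lab, pb$labels), 1)
  # determinism under the same master seed
  expect_identical(lab, consensus_partition(pb$B, n_runs = 50, seed = 11))
  # canonical labels: order of first appearance
  expect_equal(lab, match(lab, unique(lab)))
})

test_that("significance test: planted blocks significant, whole graph not", {
  pb <- planted_B(2, 8, noise = 0.05, seed = 4)
  sig <- significance_test(modularity_matrix(pb$B + 0.5), pb$labels,
                           n_perm = 2000, seed = 5)
  expect_true(all(sig$p < 0.01))
  # the all-inclusive community has q = Q = 0 and p ~ 1
  sig1 <- significance_test(modularity_matrix(pb$B + 0.5),
                            rep(1, 16), n_perm = 100, seed = 6)
  expect_equal(sig1$q, 0, tolerance = 1e-10)
  expect_equal(sig1$p, 1)
  expect_equal(unname(sig1$size), 16L)
})

test_that("permutation p-values are calibrated on structureless input", {
  set.seed(24)
  rejected <- 0; total <- 0
  for (i in 1:30) {
    n <- 40
    M <- matrix(rnorm(n^2, sd = 0.2), n, n); M <- (M + t(M)) / 2
    diag(M) <- 1
    B <- modularity_matrix(M)
    lab <- sample(rep(1:4, each = 10))   # arbitrary labels, not optimized
    sig <- significance_test(B, lab, n_perm = 500, seed = i)
    rejected <- rejected + sum(sig$p < 0.05)
    total <- total + nrow(sig)
  }
  expect_lte(rejected / total, 0.10)
})

test_that("recursive_cluster: hierarchy structure, pruning and determinism", {
  # planted 2-level hierarchy via the synthetic generator
  gen <- generate_state_switching_data(synthetic_config(
    n_parcels = 60, n_frames = 400, n_scans = 6, events_per_scan = 4,
    poisson_events = FALSE, hier = list(n_super = 2, subs_per_super = 2,
                                        perturbation = 0.6),
    amplitude = 3, noise_sd = 0.4, seed = 51))
  pats <- pool_patterns(lapply(gen$scans, scan_peak_patterns))
  C <- concordance_matrix(pats)
  H <- recursive_cluster(C, n_runs = 100, n_perm = 1000, seed = 9)
  expect_s3_class(H, "cofluct_hierarchy")
  expect_gte(H$n_levels, 3)
  # level 1 is the all-inclusive root
  expect_equal(H$levels[[1]], rep(1L, nrow(C)))
  # nestedness: each assigned pattern's community at level l+1 sits inside
  # exactly one community at level l; pruned patterns never reappear
  for (l in seq_len(H$n_levels - 1)) {
    a <- H$levels[[l]]; b <- H$levels[[l + 1]]
    expect_true(all(a[b > 0] > 0))
    for (cid in setdiff(unique(b), 0L))
      expect_equal(length(unique(a[b == cid])), 1L)
  }
  # retained communities respect size, scan-diversity and significance gates
  kept <- H$communities[H$communities$kept & H$communities$level > 1, ]
  expect_true(all(kept$size >= 5))
  expect_true(all(kept$n_scans >= 2))
  expect_true(all(kept$p < 0.05))
  # determinism
  H2 <- recursive_cluster(C, n_runs = 100, n_perm = 1000, seed = 9)
  expect_identical(H$levels, H2$levels)
  # planted super-states recovered at level 2
  m <- match_planted(pats, gen$truth)
  pl <- which(!is.na(m$super))
  expect_gte(nmi_oracle(H$levels[[2]][pl], m$super[pl]), 0.8)
})

test_that("min_size gate prunes small planted blocks", {
  # 4-member block cannot survive min_size = 5
  set.seed(26)
  n <- 24
  lab <- c(rep(1, 10), rep(2, 10), rep(3, 4))
  C <- matrix(0.05, n, n)
  for (k in 1:3) C[lab == k, lab == k] <- 0.9
  C <- C + matrix(rnorm(n^2, sd = 0.02), n, n); C <- (C + t(C)) / 2
  diag(C) <- 1
  H <- recursive_cluster(C, scan_ids = rep(c("a", "b"), n / 2),
                         n_runs = 100, n_perm = 1000, seed = 3)
  l2 <- H$levels[[2]]
  expect_true(all(l2[lab == 3] == 0))
  expect_equal(length(setdiff(unique(l2), 0L)), 2L)
})

test_that("hierarchy co-assignment follows its definition", {
  H <- structure(list(levels = list(rep(1L, 4), c(2L, 2L, 3L, 0L),
                                    c(4L, 5L, 0L, 0L)),
                      n_levels = 3L), class = "cofluct_hierarchy")
  A <- hierarchy_coassignment(H)
  expect_equal(diag(A), rep(1, 4))
  expect_equal(A[1, 2], 2 / 3)  # together at levels 1,2; apart at 3
  expect_equal(A[1, 3], 1 / 2)  # both assigned at levels 1,2 only
  expect_equal(A[1, 4], 1)      # pattern 4 only assigned at root
  expect_true(all(A >= 0 & A <= 1))
  expect_equal(hierarchical_depth(H), c(3L, 3L, 2L, 1L))
})
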