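test_that("cluster_centroid averages member patterns", {
  pat <- new_pat_fixture(rms = c(1, 1, 1))
  cen1 <- cluster_centroid(pat, 1L)
  expect_equal(cen1, edge_to_matrix(pat$edges[1, ], 5))
  # opposite patterns cancel
  pat$edges[2, ] <- -pat$edges[1, ]
  expect_equal(cluster_centroid(pat, c(1L, 2L)), matrix(0, 5, 5))
  # mean commutes with reshaping
  cen <- cluster_centroid(pat, 1:3)
  expect_equal(cen, Reduce(`+`, lapply(1:3, function(p)
    edge_to_matrix(pat$edges[p, ], 5))) / 3)
  expect_equal(cen, t(cen))
  expect_error(cluster_centroid(pat, integer(0)), "empty")
})

test_that("leading_eigenmode: rank-1 case, sign fix, scale invariance", {
  set.seed(31)
  z <- rnorm(12)
  m <- tcrossprod(z)
  em <- leading_eigenmode(m)
  expect_equal(em$var_explained, 1, tolerance = 1e-12)
  expect_equal(abs(em$vector), abs(z / sqrt(sum(z^2))), tolerance = 1e-10)
  expect_gt(em$vector[which.max(abs(em$vector))], 0)
  # two-block diagonal-free matrix: eigenvector signs split the blocks
  b <- c(rep(1, 4), rep(-1, 4))
  mb <- tcrossprod(b); diag(mb) <- 0
  emb <- leading_eigenmode(mb)
  expect_equal(length(unique(sign(emb$vector)[1:4])), 1L)
  expect_true(all(sign(emb$vector)[1:4] != sign(emb$vector)[5:8]))
  # invariant under scaling
  em3 <- leading_eigenmode(3 * m)
  expect_equal(em3$vector, em$vector)
  expect_equal(em3$var_explained, em$var_explained)
})

test_that("system_average aggregates node values per system", {
  sp <- system_partition(c("A", "A", "B"))
  expect_equal(unname(system_average(c(1, 3, 5), sp)), c(2, 5))
  expect_equal(unname(system_average(c(7, 7, 7), sp)), c(7, 7))
  # weighted recombination reproduces the global mean
  set.seed(32)
  labs <- sample(c("A", "B", "C"), 30, replace = TRUE)
  sp <- system_partition(labs)
  v <- rnorm(30)
  sm <- system_average(v, sp)
  sizes <- table(labs)[sp$systems]
  expect_equal(sum(sm * as.numeric(sizes)) / 30, mean(v))
})

test_that("correlate_with_fc is a symmetric, scale-invariant upper-tri r", {
  set.seed(33)
  A <- matrix(rnorm(64), 8, 8); A <- A + t(A)
  B <- matrix(rnorm(64), 8, 8); B <- B + t(B)
  expect_equal(correlate_with_fc(A, A), 1)
  expect_equal(correlate_with_fc(A, -A), -1)
  expect_equal(correlate_with_fc(A, B), correlate_with_fc(B, A))
  expect_equal(correlate_with_fc(A, 5 * B), correlate_with_fc(A, B))
  expect_equal(correlate_with_fc(A, B),
               cor(A[upper.tri(A)], B[upper.tri(B)]))
  expect_error(correlate_with_fc(A, matrix(1, 8, 8)), "constant")
})

test_that("centroid_parent_similarity and depth utilities", {
  gen <- generate_state_switching_data(synthetic_config(
    n_parcels = 40, n_frames = 400, n_scans = 4, events_per_scan = 5,
    poisson_events = FALSE, n_states = 2, amplitude = 3, noise_sd = 0.4,
    seed = 61))
  pats <- pool_patterns(lapply(gen$scans, scan_peak_patterns))
  C <- concordance_matrix(pats)
  H <- recursive_cluster(C, n_runs = 80, n_perm = 500, seed = 8)
  sim <- centroid_parent_similarity(H, pats)
  expect_true(all(sim$r >= -1 & sim$r <= 1))
  expect_true(all(sim$level >= 2))
  depths <- hierarchical_depth(H)
  expect_true(all(depths >= 1))
  expect_equal(length(depths), nrow(pats$edges))
  # child identical to parent membership correlates at exactly 1
  Hfake <- H
  Hfake$communities <- rbind(H$communities,
    data.frame(level = 2, id = 999, parent = 1,
               size = nrow(pats$edges), q = 0, p = 0,
               n_scans = 4, kept = TRUE))
  Hfake$members[["999"]] <- seq_len(nrow(pats$edges))
  simf <- centroid_parent_similarity(Hfake, pats)
  expect_equal(simf$r[simf$id == 999], 1)
})

test_that("depth_fc_curves modes select the right pattern sets", {
  gen <- generate_state_switching_data(synthetic_config(
    n_parcels = 30, n_frames = 300, n_scans = 2, events_per_scan = 5,
    poisson_events = FALSE, n_states = 2, amplitude = 3, noise_sd = 0.3,
    seed = 62))
  pats <- pool_patterns(lapply(gen$scans, scan_peak_patterns))
  fc <- static_fc(zscore_parcels(gen$scans[[1]]))
  # single level: all three modes agree
  d1 <- rep(1L, nrow(pats$edges))
  r <- vapply(c("level_only", "cumulative", "reverse_cumulative"),
              function(m) depth_fc_curves(pats, d1, fc, m)$r, numeric(1))
  expect_equal(unname(r[1]), unname(r[2]))
  expect_equal(unname(r[1]), unname(r[3]))
  # two levels: definitional selections
  d <- rep(c(1L, 2L), length.out = nrow(pats$edges))
  co <- depth_fc_curves(pats, d, fc, "cumulative")
  expect_equal(co$n, c(sum(d >= 1), sum(d >= 2)))
  lo <- depth_fc_curves(pats, d, fc, "level_only")
  expect_equal(lo$n, c(sum(d == 1), sum(d == 2)))
  rc <- depth_fc_curves(pats, d, fc, "reverse_cumulative")
  expect_equal(rc$n, c(sum(d <= 1), sum(d <= 2)))
  # level_only at a depth with no patterns -> missing value
  d3 <- d; d3[d3 == 1L] <- 3L
  l3 <- depth_fc_curves(pats, d3, fc, "level_only")
  expect_true(is.na(l3$r[1]))
})

test_that("cluster_composition fractions sum to one per level", {
  gen <- generate_state_switching_data(synthetic_config(
    n_parcels = 40, n_frames = 400, n_scans = 4, events_per_scan = 5,
    poisson_events = FALSE, n_states = 2, amplitude = 3, noise_sd = 0.4,
    seed = 63))
  pats <- pool_patterns(lapply(gen$scans, scan_peak_patterns))
  pats <- classify_peak_amplitude(pats, surrogate_peak_rms(gen$scans, seed = 2))
  H <- recursive_cluster(concordance_matrix(pats), n_runs = 80,
                         n_perm = 500, seed = 8)
  comp <- cluster_composition(H, pats)
  sums <- comp$by_level$frac_high + comp$by_level$frac_ns +
    comp$by_level$frac_low
  expect_equal(sums, rep(1, nrow(comp$by_level)))
  expect_true(all(comp$by_community$size >= 5))
  # all-high input -> fraction high = 1 everywhere
  pats2 <- pats
  pats2$meta$amplitude_class <- "high"
  comp2 <- cluster_composition(H, pats2)
  expect_true(all(comp2$by_level$frac_high == 1))
})
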