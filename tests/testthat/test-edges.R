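test_that("z-scoring uses sample std over retained frames", {
  ts <- make_ts(cbind(c(1, 2, 3), c(5, 1, 3)))
  z <- zscore_parcels(ts, runs = data.frame(scan_id = "s1", start = 0L,
                                            end = 3L))
  expect_equal(z[, 1], c(-1, 0, 1))
  expect_equal(mean(z[, 2]), 0, tolerance = 1e-14)
  expect_equal(sd(z[, 2]), 1, tolerance = 1e-14)
  # constant parcel -> degenerate-input error naming the parcel
  tc <- make_ts(cbind(c(1, 2, 3), c(7, 7, 7)))
  expect_error(zscore_parcels(tc, runs = data.frame(scan_id = "s1",
                                                    start = 0L, end = 3L)),
               "zero-variance.*p2")
})

test_that("edge_frame is the upper triangle of the z outer product", {
  expect_equal(edge_frame(c(1, -1)), -1)
  # column-major upper triangle of outer([2,3,-1]): (1,2)=6,(1,3)=-2,(2,3)=-3
  expect_equal(edge_frame(c(2, 3, -1)), c(6, -2, -3))
  set.seed(4)
  z <- rnorm(7)
  expect_equal(sign(edge_frame(z)), edge_frame(sign(z)) * 1)
  m <- edge_to_matrix(edge_frame(z), 7)
  expect_equal(m, tcrossprod(z) - diag(z^2))
})

test_that("static_fc matches Pearson correlation exactly", {
  set.seed(5)
  X <- matrix(rnorm(200), 20, 10)
  X[, 2] <- X[, 1]          # identical pair
  X[, 3] <- -X[, 1]         # anti-correlated pair
  ts <- make_ts(X)
  z <- zscore_parcels(ts)
  fc <- static_fc(z)
  expect_equal(fc, cor(X), tolerance = 1e-12)
  expect_equal(fc[1, 2], 1)
  expect_equal(fc[1, 3], -1)
})

test_that("exact decomposition: mean edge time series reproduces FC", {
  set.seed(6)
  ts <- make_ts(matrix(rnorm(30 * 8), 30, 8))
  z <- zscore_parcels(ts)
  E <- t(apply(z, 1, edge_frame))
  fc <- static_fc(z)
  expect_equal(colMeans(E) * nrow(z) / (nrow(z) - 1), fc[upper.tri(fc)],
               tolerance = 1e-10)
})

test_that("rms_series matches direct edge computation and closed form", {
  set.seed(7)
  ts <- make_ts(matrix(rnorm(15 * 6), 15, 6))
  z <- zscore_parcels(ts)
  r <- rms_series(z)
  direct <- apply(z, 1, function(row) sqrt(mean(edge_frame(row)^2)))
  expect_equal(r, direct, tolerance = 1e-12)
  expect_true(all(r >= 0))
  expect_equal(rms_series(z, mode = "sumsq"),
               apply(z, 1, function(row) sum(edge_frame(row)^2)),
               tolerance = 1e-12)
  # two-parcel frame z = (1, -1): single edge -1 -> R = 1
  expect_equal(rms_series(matrix(c(1, -1), 1, 2)), 1)
  expect_equal(rms_series(matrix(0, 1, 5)), 0)
})

test_that("peak detection: segments, prominence, separation", {
  # single clear peak
  s <- detect_peak_segments(c(0.5, 3.0, 0.5), tr = 1)
  expect_equal(nrow(s), 1L)
  expect_equal(s$peak, 2L)
  expect_equal(s$relative_rms, 2.5)
  # both candidate peaks below prominence threshold
  s <- detect_peak_segments(c(1, 1.2, 1, 1.21, 1), tr = 1,
                            min_relative_rms = 0.25)
  expect_equal(nrow(s), 0L)
  expect_equal(attr(s, "n_candidates"), 2L)
  # two peaks 5 s apart: greedy suppression keeps the larger prominence
  r <- c(0, 1, 0, 2, 0)
  s <- detect_peak_segments(r, tr = 2.5, min_separation_s = 10)
  expect_equal(nrow(s), 1L)
  expect_equal(s$peak, 4L)
  # same series, separation smaller than distance: both kept
  s <- detect_peak_segments(r, tr = 10, min_separation_s = 10)
  expect_equal(nrow(s), 2L)
})

test_that("peak detection properties: mirror symmetry and local maxima", {
  set.seed(8)
  for (i in 1:15) {
    r <- abs(rnorm(60, mean = 1, sd = 0.5))
    s <- detect_peak_segments(r, tr = 1, min_separation_s = 0)
    if (nrow(s) > 0) {
      expect_true(all(r[s$peak] >= r[pmax(s$peak - 1, 1)]))
      expect_true(all(r[s$peak] >= r[pmin(s$peak + 1, length(r))]))
      expect_true(all(s$left < s$peak & s$peak < s$right))
    }
    sm <- detect_peak_segments(rev(r), tr = 1, min_separation_s = 0)
    expect_setequal(length(r) + 1 - sm$peak, s$peak)
  }
})

test_that("scan_peak_patterns extracts single-frame rank-1 patterns", {
  gen <- generate_state_switching_data(synthetic_config(
    n_parcels = 20, n_frames = 200, n_scans = 1, n_states = 2,
    events_per_scan = 4, poisson_events = FALSE, noise_sd = 0.2, seed = 21))
  ts <- gen$scans[[1]]
  pat <- scan_peak_patterns(ts)
  expect_gt(nrow(pat$edges), 0)
  z <- zscore_parcels(ts)
  for (p in seq_len(nrow(pat$edges))) {
    f <- pat$meta$frame[p] + 1L
    expect_equal(pat$edges[p, ], edge_frame(z[f, ]), tolerance = 1e-12)
    # stored rms equals RMS recomputed from the vector
    expect_equal(pat$meta$rms[p], sqrt(mean(pat$edges[p, ]^2)),
                 tolerance = 1e-12)
    # single-frame pattern is rank 1: leading eigenmode explains everything
    em <- leading_eigenmode(edge_to_matrix(pat$edges[p, ], 20) +
                            diag(z[f, ]^2))
    expect_equal(em$var_explained, 1, tolerance = 1e-10)
  }
  expect_equal(unname(pat$funnel["peaks"]), nrow(pat$edges))
})

test_that("amplitude classification against a null distribution", {
  pat <- new_pat_fixture()
  null <- c(1, 1.1, 1.2, 1.3, 1.4)
  cls <- classify_peak_amplitude(pat, null)
  expect_equal(cls$meta$amplitude_class, c("high", "ns", "low"))
  expect_warning(cu <- classify_peak_amplitude(pat, numeric(0)), "empty null")
  expect_true(all(cu$meta$amplitude_class == "unclassified"))
})

test_that("planted high-amplitude events are classified high", {
  gen <- generate_state_switching_data(synthetic_config(
    n_parcels = 30, n_frames = 400, n_scans = 2, n_states = 1,
    events_per_scan = 6, poisson_events = FALSE, amplitude = 3,
    noise_sd = 0.5, seed = 31))
  pats <- pool_patterns(lapply(gen$scans, scan_peak_patterns))
  null <- surrogate_peak_rms(gen$scans, seed = 5)
  pats <- classify_peak_amplitude(pats, null)
  m <- match_planted(pats, gen$truth)
  planted <- which(!is.na(m$state))
  expect_gt(length(planted), 6)
  expect_gte(mean(pats$meta$amplitude_class[planted] == "high"), 0.9)
})

test_that("off-peak resampling yields valid, structured p-values", {
  gen <- generate_state_switching_data(synthetic_config(
    n_parcels = 20, n_frames = 300, n_scans = 1, n_states = 2,
    events_per_scan = 5, poisson_events = FALSE, amplitude = 3,
    noise_sd = 0.4, seed = 41))
  ts <- gen$scans[[1]]
  pat <- scan_peak_patterns(ts)
  z <- zscore_parcels(ts)
  res <- offpeak_resampling_test(z, pat, n_resamples = 50, seed = 2)
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_equal(res$p, t(res$p))
  # within-state pairs (planted) should move away from their peaks more
  # detectably than cross-state pairs: lower median p within
  m <- match_planted(pat, gen$truth)
  pl <- which(!is.na(m$state))
  if (length(pl) >= 4) {
    same <- outer(m$state[pl], m$state[pl], "==") & upper.tri(diag(length(pl)))
    diff <- (!outer(m$state[pl], m$state[pl], "==")) & upper.tri(diag(length(pl)))
    expect_lt(median(res$p[pl, pl][same]), median(res$p[pl, pl][diff]))
  }
})
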