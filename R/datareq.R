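#' Split-half, scan-incremental centroid convergence
#'
#' How much data is needed for stable cluster centroids?  Cluster labels are
#' taken from the full-data hierarchy and held fixed.  Scans are repeatedly
#' split into two halves; reference centroids are computed per cluster from
#' all of half 1, while half 2 is rebuilt one scan at a time (random order)
#' and after each added scan the accumulating centroid of every cluster is
#' correlated (Pearson, edge vectors) with the reference.
#'
#' @param patterns pooled `cofluct_patterns`.
#' @param labels per-pattern cluster labels (0/NA = unassigned, ignored).
#' @param n_splits number of random splits (default 100).
#' @param seed RNG seed.
#' @return A `split_half_result`: list with `sim` and `samples`
#'   (splits x increments x clusters arrays; `samples` is the cumulative
#'   member count of the cluster in the growing half), `clusters`,
#'   `n_half`, `sim_mean` / `samples_mean` (increments x clusters, averaged
#'   over splits, `NA` where a cluster was absent).
#' @export
split_half_convergence <- function(patterns, labels, n_splits = 100,
                                   seed = 1L) {
  scan_ids <- patterns$meta$scan_id
  scans <- unique(scan_ids)
  if (length(scans) < 4L) stop("need at least 4 scans to split")
  labels <- as.integer(labels)
  keep <- !is.na(labels) & labels > 0L
  clusters <- sort(unique(labels[keep]))
  n_half <- floor(length(scans) / 2)
  sim <- array(NA_real_, c(n_splits, n_half, length(clusters)))
  samp <- array(NA_real_, c(n_splits, n_half, length(clusters)))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  X <- patterns$edges
  for (s in seq_len(n_splits)) {
    perm <- sample(scans)
    half1 <- perm[seq_len(n_half)]
    half2 <- perm[(n_half + 1L):(2L * n_half)]
    ref <- lapply(clusters, function(cl) {
      idx <- which(keep & labels == cl & scan_ids %in% half1)
      if (length(idx) == 0L) NULL else colMeans(X[idx, , drop = FALSE])
    })
    for (inc in seq_len(n_half)) {
      acc <- half2[seq_len(inc)]
      for (ci in seq_along(clusters)) {
        if (is.null(ref[[ci]])) next
        idx <- which(keep & labels == clusters[ci] & scan_ids %in% acc)
        samp[s, inc, ci] <- length(idx)
        if (length(idx) == 0L) next
        cen <- colMeans(X[idx, , drop = FALSE])
        if (sd(cen) == 0 || sd(ref[[ci]]) == 0) next
        sim[s, inc, ci] <- cor(cen, ref[[ci]])
      }
    }
  }
  structure(list(sim = sim, samples = samp, clusters = clusters,
                 n_half = n_half,
                 sim_mean = apply(sim, c(2, 3), mean, na.rm = TRUE),
                 samples_mean = apply(samp, c(2, 3), mean, na.rm = TRUE)),
            class = "split_half_result")
}

#' Reindex convergence curves by cumulative sample count
#'
#' Interpolates each cluster's scan-indexed mean similarity curve onto a
#' common grid of cumulative sample counts, enabling the comparison of
#' clusters with different per-scan frequencies on equal-sample footing.
#'
#' @param res a `split_half_result`.
#' @param grid sample-count grid; defaults to the overlap of all clusters'
#'   observed ranges (20 points).
#' @return List with `grid` and `sim` (grid x clusters matrix).
#' @export
reindex_by_samples <- function(res, grid = NULL) {
  K <- length(res$clusters)
  xs <- lapply(seq_len(K), function(ci) res$samples_mean[, ci])
  if (is.null(grid)) {
    lo <- max(vapply(xs, min, numeric(1), na.rm = TRUE))
    hi <- min(vapply(xs, max, numeric(1), na.rm = TRUE))
    if (!(hi > lo)) stop("cluster sample ranges do not overlap")
    grid <- seq(lo, hi, length.out = 20L)
  }
  sim <- vapply(seq_len(K), function(ci) {
    ok <- is.finite(xs[[ci]]) & is.finite(res$sim_mean[, ci])
    stats::approx(xs[[ci]][ok], res$sim_mean[ok, ci], xout = grid,
                  rule = 1)$y
  }, numeric(length(grid)))
  list(grid = grid, sim = sim)
}

#' Per-scan cluster frequency
#'
#' Number of patterns from each cluster occurring in each scan (absent
#' combinations count as 0), with mean and sd across scans.
#'
#' @param labels per-pattern cluster labels.
#' @param scan_ids per-pattern scan identifiers.
#' @return List with `counts` (scan x cluster table) and `summary`
#'   (cluster, mean, sd).
#' @export
cluster_frequency_per_scan <- function(labels, scan_ids) {
  labels <- as.integer(labels)
  keep <- !is.na(labels) & labels > 0L
  tab <- table(factor(scan_ids[keep], levels = unique(scan_ids)),
               factor(labels[keep]))
  counts <- as.matrix(tab)
  summary <- data.frame(cluster = as.integer(colnames(counts)),
                        mean = colMeans(counts),
                        sd = apply(counts, 2L, sd))
  rownames(summary) <- NULL
  list(counts = counts, summary = summary)
}

#' Cross-half pattern-to-centroid similarity
#'
#' Splits patterns by scan membership; per cluster, correlates each half-A
#' member pattern with the half-B centroid and averages.
#'
#' @param patterns pooled `cofluct_patterns`.
#' @param labels per-pattern cluster labels.
#' @param scans_a character vector of scan ids forming half A; half B is the
#'   complement.
#' @return data.frame `cluster`, `n`, `mean_r` (`NA` when either half lacks
#'   the cluster).
#' @export
pattern_to_centroid_similarity <- function(patterns, labels, scans_a) {
  scan_ids <- patterns$meta$scan_id
  labels <- as.integer(labels)
  keep <- !is.na(labels) & labels > 0L
  in_a <- scan_ids %in% scans_a
  clusters <- sort(unique(labels[keep]))
  out <- lapply(clusters, function(cl) {
    ia <- which(keep & labels == cl & in_a)
    ib <- which(keep & labels == cl & !in_a)
    if (length(ia) == 0L || length(ib) == 0L)
      return(data.frame(cluster = cl, n = length(ia), mean_r = NA_real_))
    cen <- colMeans(patterns$edges[ib, , drop = FALSE])
    r <- apply(patterns$edges[ia, , drop = FALSE], 1L, cor, y = cen)
    data.frame(cluster = cl, n = length(ia), mean_r = mean(r))
  })
  do.call(rbind, out)
}
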