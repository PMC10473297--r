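#' Z-score parcel time series over retained frames
#'
#' Means and standard deviations are estimated per parcel over *all* retained
#' (low-motion, padded, min-run-filtered) frames of the scan, pooled across
#' runs; sample standard deviation (denominator n - 1) is used so that the
#' temporal mean of the edge time series reproduces Pearson correlation
#' exactly.
#'
#' @param ts a [parcel_ts()] object.
#' @param runs run table from [segment_usable_runs()]; defaults to
#'   re-segmenting `ts`.
#' @return Numeric matrix of the same shape as `ts$data`, z-scored per
#'   parcel; frames outside the retained runs are `NA`.  Attribute
#'   `retained` holds the logical mask of retained frames.
#' @export
zscore_parcels <- function(ts, runs = segment_usable_runs(ts)) {
  stopifnot(inherits(ts, "parcel_ts"))
  T <- nrow(ts$data)
  retained <- rep(FALSE, T)
  for (k in seq_len(nrow(runs)))
    retained[(runs$start[k] + 1L):runs$end[k]] <- TRUE
  if (sum(retained) < 3L)
    stop("fewer than 3 retained frames in scan ", ts$scan_id)
  x <- ts$data[retained, , drop = FALSE]
  mu <- colMeans(x)
  s <- apply(x, 2L, sd)
  if (any(s == 0))
    stop("degenerate input: zero-variance parcel(s) ",
         paste(head(ts$parcel_ids[s == 0], 5), collapse = ", "))
  z <- matrix(NA_real_, T, ncol(ts$data))
  z[retained, ] <- sweep(sweep(x, 2L, mu, "-"), 2L, s, "/")
  attr(z, "retained") <- retained
  z
}

#' Edge co-fluctuation vector of a single frame
#'
#' The instantaneous co-fluctuation between parcels i and j is the product of
#' their z-scores, `z_i(t) * z_j(t)`; a frame's edge vector is the upper
#' triangle (column-major, i < j) of the rank-1 outer product `z z'`.
#'
#' @param z_row numeric vector of length N (one z-scored frame).
#' @return Numeric vector of length `N (N - 1) / 2`.
#' @export
edge_frame <- function(z_row) {
  if (any(!is.finite(z_row))) stop("non-finite z-scores")
  op <- tcrossprod(z_row)
  op[upper.tri(op)]
}

#' Reshape an edge vector back to a symmetric matrix
#'
#' @param v edge vector of length `N (N - 1) / 2` in [edge_frame()] order.
#' @param N number of parcels.
#' @return N x N symmetric matrix with zero diagonal.
#' @export
edge_to_matrix <- function(v, N) {
  m <- matrix(0, N, N)
  m[upper.tri(m)] <- v
  m + t(m)
}

#' Static functional connectivity from z-scored series
#'
#' Pearson correlation computed as the temporal average of co-fluctuation
#' over retained frames, `r_ij = 1/(T-1) sum_t z_i(t) z_j(t)`.
#'
#' @param z z-scored matrix from [zscore_parcels()].
#' @return N x N correlation matrix (symmetric, unit diagonal).
#' @export
static_fc <- function(z) {
  retained <- attr(z, "retained") %||% rep(TRUE, nrow(z))
  x <- z[retained, , drop = FALSE]
  if (nrow(x) < 3L) stop("need at least 3 retained frames")
  fc <- crossprod(x) / (nrow(x) - 1)
  diag(fc) <- 1
  fc
}

#' Global co-fluctuation amplitude (RMS) of each frame in a run
#'
#' `R(t) = sqrt( mean_{i<j} r_ij(t)^2 )` by default.  The sum of squared edge
#' co-fluctuations is computed in closed form per frame,
#' `sum_{i<j} (z_i z_j)^2 = ((sum z^2)^2 - sum z^4) / 2`, so the full
#' edge x time matrix is never materialized.  Any monotone variant (sum of
#' squares with or without the square root) preserves peak locations; the
#' raw sum of squares is available as `mode = "sumsq"`.
#'
#' @param z z-scored matrix from [zscore_parcels()].
#' @param run one row of the run table (`start`, `end`, 0-based half-open),
#'   or `NULL` to use all rows of `z`.
#' @param mode `"rms"` (default) or `"sumsq"`.
#' @return Numeric vector of per-frame amplitudes (length = run length).
#' @export
rms_series <- function(z, run = NULL, mode = c("rms", "sumsq")) {
  mode <- match.arg(mode)
  idx <- if (is.null(run)) seq_len(nrow(z)) else (run$start + 1L):run$end
  x <- z[idx, , drop = FALSE]
  N <- ncol(x)
  s2 <- rowSums(x^2)
  s4 <- rowSums(x^4)
  ss <- (s2^2 - s4) / 2
  ss[ss < 0] <- 0  # guard tiny negative rounding
  if (mode == "sumsq") ss else sqrt(ss / (N * (N - 1) / 2))
}

#' Trough-to-trough segmentation and peak detection
#'
#' Troughs are strict local minima of the RMS series; run endpoints act as
#' additional segment boundaries.  Each trough-to-trough segment contains one
#' peak (its maximum; leftmost frame on plateaus).  A peak's relative RMS
#' (prominence) is its height minus the larger of its two bounding trough
#' heights; peaks with relative RMS <= `min_relative_rms` are dropped.
#' Surviving peaks closer in time than `min_separation_s` are thinned
#' greedily: candidates are visited in decreasing relative RMS (ties to the
#' earlier frame) and a peak is kept only if no already-kept peak lies within
#' `ceiling(min_separation_s / tr)` frames.
#'
#' @param rms numeric RMS vector for a single run.
#' @param tr repetition time in seconds.
#' @param min_relative_rms prominence threshold (default 0.25).
#' @param min_separation_s minimum peak separation in seconds (default 10).
#' @return data.frame with 1-based in-run columns `left`, `peak`, `right`,
#'   plus `peak_rms` and `relative_rms`.  Attribute `n_candidates` records
#'   the pre-filter segment count.  Runs shorter than 3 frames yield zero
#'   rows.
#' @export
detect_peak_segments <- function(rms, tr, min_relative_rms = 0.25,
                                 min_separation_s = 10) {
  n <- length(rms)
  empty <- data.frame(left = integer(), peak = integer(), right = integer(),
                      peak_rms = numeric(), relative_rms = numeric())
  attr(empty, "n_candidates") <- 0L
  if (n < 3L) return(empty)
  interior <- 2L:(n - 1L)
  minima <- interior[rms[interior] < rms[interior - 1L] &
                     rms[interior] < rms[interior + 1L]]
  troughs <- unique(c(1L, minima, n))
  k <- length(troughs) - 1L
  left <- troughs[seq_len(k)]
  right <- troughs[seq_len(k) + 1L]
  peak <- integer(k); pk <- numeric(k)
  for (s in seq_len(k)) {
    seg <- left[s]:right[s]
    peak[s] <- seg[which.max(rms[seg])]
    pk[s] <- rms[peak[s]]
  }
  rel <- pk - pmax(rms[left], rms[right])
  seg <- data.frame(left = left, peak = peak, right = right,
                    peak_rms = pk, relative_rms = rel)
  n_candidates <- nrow(seg)
  seg <- seg[seg$relative_rms > min_relative_rms, , drop = FALSE]
  # greedy suppression of peaks closer than the separation window
  if (nrow(seg) > 1L) {
    min_sep <- ceiling(min_separation_s / tr)
    ord <- order(-seg$relative_rms, seg$peak)
    kept <- integer(0)
    for (i in ord) {
      if (!any(abs(seg$peak[kept] - seg$peak[i]) < min_sep))
        kept <- c(kept, i)
    }
    seg <- seg[sort(kept), , drop = FALSE]
  }
  rownames(seg) <- NULL
  attr(seg, "n_candidates") <- n_candidates
  seg
}

#' Extract peak co-fluctuation patterns from one scan
#'
#' Runs the full per-scan funnel: censor padding and run segmentation,
#' pooled z-scoring, per-run RMS, trough-to-trough peak detection with
#' prominence and separation filters, and extraction of the single-frame
#' edge vector at each surviving peak (no segment averaging).
#'
#' @param ts a [parcel_ts()] object.
#' @param pad_frames,min_run see [segment_usable_runs()].
#' @param min_relative_rms,min_separation_s see [detect_peak_segments()].
#' @param rms_mode see [rms_series()].
#' @return A `cofluct_patterns` object: list with `edges` (patterns x edges
#'   matrix), `meta` (scan_id, frame — 0-based within scan —, rms,
#'   relative_rms, amplitude_class), `segments` (global 1-based left/peak/
#'   right, for off-peak resampling), `n_parcels`, and `funnel` counts
#'   (segments, after_prominence_and_separation).
#' @export
scan_peak_patterns <- function(ts, pad_frames = 2L, min_run = 5L,
                               min_relative_rms = 0.25, min_separation_s = 10,
                               rms_mode = "rms") {
  runs <- segment_usable_runs(ts, pad_frames, min_run)
  N <- ncol(ts$data)
  E <- N * (N - 1L) / 2L
  if (nrow(runs) == 0L) {
    return(new_patterns(matrix(numeric(0), 0L, E), meta_empty(), N,
                        segments = seg_empty(),
                        funnel = c(segments = 0L, peaks = 0L)))
  }
  z <- zscore_parcels(ts, runs)
  segs <- list(); n_cand <- 0L
  for (k in seq_len(nrow(runs))) {
    run <- runs[k, ]
    r <- rms_series(z, run, mode = rms_mode)
    s <- detect_peak_segments(r, ts$tr, min_relative_rms, min_separation_s)
    n_cand <- n_cand + attr(s, "n_candidates")
    if (nrow(s) > 0L) {
      s$left <- s$left + run$start; s$peak <- s$peak + run$start
      s$right <- s$right + run$start  # global 1-based row indices into z
      segs[[length(segs) + 1L]] <- s
    }
  }
  segs <- if (length(segs)) do.call(rbind, segs) else seg_empty()
  P <- nrow(segs)
  edges <- matrix(0, P, E)
  for (p in seq_len(P)) edges[p, ] <- edge_frame(z[segs$peak[p], ])
  meta <- data.frame(scan_id = rep(ts$scan_id, P),
                     frame = segs$peak - 1L,
                     rms = segs$peak_rms,
                     relative_rms = segs$relative_rms,
                     amplitude_class = rep("unclassified", P),
                     stringsAsFactors = FALSE)
  new_patterns(edges, meta, N, segments = segs,
               funnel = c(segments = n_cand, peaks = P))
}

seg_empty <- function() data.frame(left = integer(), peak = integer(),
                                   right = integer(), peak_rms = numeric(),
                                   relative_rms = numeric())

meta_empty <- function() data.frame(scan_id = character(), frame = integer(),
                                    rms = numeric(), relative_rms = numeric(),
                                    amplitude_class = character(),
                                    stringsAsFactors = FALSE)

new_patterns <- function(edges, meta, n_parcels, segments = NULL,
                         funnel = NULL) {
  structure(list(edges = edges, meta = meta, n_parcels = n_parcels,
                 segments = segments, funnel = funnel),
            class = "cofluct_patterns")
}

#' @export
print.cofluct_patterns <- function(x, ...) {
  cat(sprintf("cofluct_patterns: %d peak patterns, %d parcels (%d edges), %d scan(s)\n",
              nrow(x$edges), x$n_parcels, ncol(x$edges),
              length(unique(x$meta$scan_id))))
  invisible(x)
}

#' Pool peak patterns across scans
#'
#' @param pattern_list list of `cofluct_patterns` sharing a parcel set.
#' @return A single pooled `cofluct_patterns` object.
#' @export
pool_patterns <- function(pattern_list) {
  stopifnot(length(pattern_list) >= 1L)
  N <- unique(vapply(pattern_list, function(p) p$n_parcels, integer(1)))
  if (length(N) != 1L) stop("pattern sets have different parcel counts")
  funnels <- lapply(pattern_list, function(p) p$funnel)
  funnel <- if (all(!vapply(funnels, is.null, logical(1))))
    Reduce(`+`, funnels) else NULL
  new_patterns(do.call(rbind, lapply(pattern_list, function(p) p$edges)),
               do.call(rbind, lapply(pattern_list, function(p) p$meta)),
               N, funnel = funnel)
}

#' Classify peak amplitudes against a null RMS distribution
#'
#' Peaks are labeled `high` if their RMS exceeds the `hi_pct` percentile of
#' the null peak-RMS distribution (from circular-shift surrogates), `low` if
#' below the `lo_pct` percentile, and `ns` otherwise.
#'
#' @param patterns a `cofluct_patterns` object.
#' @param null_peak_rms numeric vector of surrogate peak RMS values.
#' @param hi_pct,lo_pct percentile cutoffs (defaults 97.5 and 2.5).
#' @return `patterns` with `meta$amplitude_class` filled in.
#' @export
classify_peak_amplitude <- function(patterns, null_peak_rms,
                                    hi_pct = 97.5, lo_pct = 2.5) {
  if (length(null_peak_rms) == 0L) {
    warning("empty null distribution; amplitude classes left unclassified")
    return(patterns)
  }
  hi <- quantile(null_peak_rms, hi_pct / 100, names = FALSE)
  lo <- quantile(null_peak_rms, lo_pct / 100, names = FALSE)
  cls <- rep("ns", nrow(patterns$edges))
  cls[patterns$meta$rms > hi] <- "high"
  cls[patterns$meta$rms < lo] <- "low"
  patterns$meta$amplitude_class <- cls
  patterns
}

#' Off-peak resampling control
#'
#' Tests whether pairwise pattern concordance depends on sampling exactly the
#' peak frame: in each resample every pattern is replaced by the edge vector
#' of a uniformly random non-peak frame from its own trough-to-trough
#' segment, a null concordance matrix is computed, and
#' `p(i,j)` = fraction of resamples with null concordance >= observed.
#'
#' @param z z-scored matrix of the scan.
#' @param patterns single-scan `cofluct_patterns` with its `segments` table.
#' @param n_resamples number of resamples (default 1000).
#' @param seed RNG seed.
#' @return List with `p` (symmetric p-value matrix) and `observed`
#'   concordance matrix.
#' @export
offpeak_resampling_test <- function(z, patterns, n_resamples = 1000,
                                    seed = 1) {
  segs <- patterns$segments
  if (is.null(segs)) stop("patterns carry no segment table (pooled set?)")
  P <- nrow(segs)
  obs <- concordance_matrix(patterns)
  cnt <- matrix(0, P, P)
  alt <- lapply(seq_len(P), function(p) {
    f <- setdiff(segs$left[p]:segs$right[p], segs$peak[p])
    if (length(f) == 0L) segs$peak[p] else f
  })
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (r in seq_len(n_resamples)) {
    frames <- vapply(alt, function(f) if (length(f) == 1L) f else sample(f, 1L),
                     numeric(1))
    ed <- t(vapply(frames, function(f) edge_frame(z[f, ]),
                   numeric(ncol(patterns$edges))))
    nullC <- lin_concordance_matrix(ed)
    cnt <- cnt + (nullC >= obs)
  }
  list(p = cnt / n_resamples, observed = obs)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
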