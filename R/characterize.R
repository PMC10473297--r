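#' Community centroid co-fluctuation matrix
#'
#' Element-wise mean of the member patterns' edge vectors, reshaped to a
#' symmetric node x node matrix with zero diagonal.
#'
#' @param patterns a `cofluct_patterns` object.
#' @param members integer indices of the member patterns.
#' @return N x N symmetric centroid matrix.
#' @export
cluster_centroid <- function(patterns, members) {
  if (length(members) == 0L) stop("empty member set")
  v <- colMeans(patterns$edges[members, , drop = FALSE])
  edge_to_matrix(v, patterns$n_parcels)
}

#' Leading eigenmode of a co-fluctuation matrix
#'
#' Eigenvector of the largest-magnitude eigenvalue; co-fluctuation matrices
#' are indefinite, so variance explained is normalized by the sum of
#' absolute eigenvalues, `|lambda_1| / sum_k |lambda_k|`.  The sign is fixed
#' so the largest-magnitude element is positive.
#'
#' @param centroid symmetric matrix.
#' @return List with `vector` (unit norm), `value`, `var_explained`.
#' @export
leading_eigenmode <- function(centroid) {
  e <- eigen(centroid, symmetric = TRUE)
  k <- which.max(abs(e$values))
  v <- e$vectors[, k]
  if (v[which.max(abs(v))] < 0) v <- -v
  tot <- sum(abs(e$values))
  list(vector = v, value = e$values[k],
       var_explained = if (tot > 0) abs(e$values[k]) / tot else 0)
}

#' Average a node vector within each system
#'
#' Summarizes e.g. a leading eigenvector at the level of canonical systems
#' without recomputing eigenvectors.
#'
#' @param vec numeric vector of length N.
#' @param partition a [system_partition()].
#' @return Named numeric vector of per-system means, in system order.
#' @export
system_average <- function(vec, partition) {
  stopifnot(inherits(partition, "system_partition"),
            length(vec) == length(partition$labels))
  out <- vapply(partition$systems,
                function(s) mean(vec[partition$labels == s]), numeric(1))
  setNames(out, partition$systems)
}

#' Upper-triangle Pearson correlation between two matrices
#'
#' @param A,B square matrices of equal size.
#' @return Pearson r over the vectorized `i < j` entries.
#' @export
correlate_with_fc <- function(A, B) {
  stopifnot(all(dim(A) == dim(B)))
  a <- A[upper.tri(A)]; b <- B[upper.tri(B)]
  if (sd(a) == 0 || sd(b) == 0)
    stop("constant upper triangle; correlation undefined")
  cor(a, b)
}

#' Correlation of each child centroid with its parent centroid
#'
#' @param H a `cofluct_hierarchy`.
#' @param patterns the clustered `cofluct_patterns`.
#' @param kept_only restrict to retained communities (default TRUE).
#' @return data.frame `id`, `parent`, `level`, `r`.
#' @export
centroid_parent_similarity <- function(H, patterns, kept_only = TRUE) {
  cm <- H$communities
  cm <- cm[!is.na(cm$parent) & (!kept_only | cm$kept), , drop = FALSE]
  r <- vapply(seq_len(nrow(cm)), function(k) {
    child <- cluster_centroid(patterns, H$members[[as.character(cm$id[k])]])
    parent <- cluster_centroid(patterns, H$members[[as.character(cm$parent[k])]])
    correlate_with_fc(child, parent)
  }, numeric(1))
  data.frame(id = cm$id, parent = cm$parent, level = cm$level, r = r)
}

#' FC correspondence of mean patterns by hierarchical depth
#'
#' For each level `l`, averages the patterns selected by `mode` and
#' correlates the resulting matrix with static FC:
#' `level_only` uses patterns of depth exactly `l`; `cumulative` those of
#' depth >= `l` (current level and below, i.e. also surviving deeper);
#' `reverse_cumulative` those of depth <= `l`.
#'
#' @param patterns `cofluct_patterns`.
#' @param depths integer depths from [hierarchical_depth()].
#' @param fc static FC matrix.
#' @param mode selection rule.
#' @return data.frame `level`, `n`, `r` (`r` is `NA` for empty selections).
#' @export
depth_fc_curves <- function(patterns, depths, fc,
                            mode = c("level_only", "cumulative",
                                     "reverse_cumulative")) {
  mode <- match.arg(mode)
  L <- max(depths)
  out <- lapply(seq_len(L), function(l) {
    sel <- switch(mode,
                  level_only = which(depths == l),
                  cumulative = which(depths >= l),
                  reverse_cumulative = which(depths <= l))
    if (length(sel) == 0L)
      return(data.frame(level = l, n = 0L, r = NA_real_))
    m <- cluster_centroid(patterns, sel)
    data.frame(level = l, n = length(sel), r = correlate_with_fc(m, fc))
  })
  do.call(rbind, out)
}

#' Cluster composition by peak amplitude class
#'
#' At each hierarchical level, the fraction of still-assigned patterns
#' labeled high / n.s. / low, plus per-community class fractions and mean
#' RMS.
#'
#' @param H a `cofluct_hierarchy`.
#' @param patterns classified `cofluct_patterns` (see
#'   [classify_peak_amplitude()]).
#' @return List with `by_level` (level, frac_high, frac_ns, frac_low, n) and
#'   `by_community` (id, level, size, frac_high, frac_ns, frac_low,
#'   mean_rms).
#' @export
cluster_composition <- function(H, patterns) {
  cls <- patterns$meta$amplitude_class
  rms <- patterns$meta$rms
  frac <- function(idx) {
    n <- length(idx)
    c(frac_high = sum(cls[idx] == "high") / n,
      frac_ns = sum(cls[idx] == "ns") / n,
      frac_low = sum(cls[idx] == "low") / n)
  }
  by_level <- do.call(rbind, lapply(seq_len(H$n_levels), function(l) {
    idx <- which(H$levels[[l]] > 0L)
    if (length(idx) == 0L) return(NULL)
    data.frame(level = l, t(frac(idx)), n = length(idx))
  }))
  kept <- H$communities[H$communities$kept, ]
  by_comm <- do.call(rbind, lapply(seq_len(nrow(kept)), function(k) {
    idx <- H$members[[as.character(kept$id[k])]]
    data.frame(id = kept$id[k], level = kept$level[k], size = length(idx),
               t(frac(idx)), mean_rms = mean(rms[idx]))
  }))
  list(by_level = by_level, by_community = by_comm)
}
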