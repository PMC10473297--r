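#' Sign bipartition of a z-scored frame
#'
#' At any instant the co-fluctuation pattern splits the parcels into exactly
#' two groups by the sign of activity: `r_ij(t) > 0` iff parcels i and j are
#' on the same side of their mean.  Zeros go to the "below" group.
#'
#' @param z_frame numeric z-scored frame of length N.
#' @return Integer 0/1 vector; attribute `degenerate` is `TRUE` when all
#'   parcels fall in one group.
#' @export
frame_bipartition <- function(z_frame) {
  out <- as.integer(z_frame > 0)
  attr(out, "degenerate") <- length(unique(out)) < 2L
  out
}

#' Mean co-assignment matrix from framewise bipartitions
#'
#' Entry (i, j) is the fraction of frames on which parcels i and j carry the
#' same sign label; despite discarding amplitudes this closely recapitulates
#' static connectivity structure.
#'
#' @param bips T x N matrix of 0/1 labels (one row per frame), e.g.
#'   `t(apply(z, 1, frame_bipartition))`.
#' @return N x N symmetric matrix in `[0, 1]` with unit diagonal.
#' @export
coassignment_from_bipartitions <- function(bips) {
  bips <- as.matrix(bips)
  T <- nrow(bips)
  stopifnot(T >= 1L)
  (crossprod(bips) + crossprod(1 - bips)) / T
}

#' Enumerate all system-level bipartition templates
#'
#' All `2^(S-1) - 1` nontrivial two-group partitions of the S systems, up to
#' complement (canonical form: the group containing the first system is
#' labeled 1), each expanded to a node-level 0/1 label vector via the
#' parcel-to-system map.
#'
#' @param partition a [system_partition()]; 2 <= S <= 20.
#' @return A `template_set`: list with `system_labels`
#'   (templates x S 0/1 matrix), `node_labels` (templates x N), `systems`.
#' @export
enumerate_system_templates <- function(partition) {
  stopifnot(inherits(partition, "system_partition"))
  S <- length(partition$systems)
  if (S > 20L)
    stop("S = ", S, " systems would give 2^(S-1)-1 templates; ",
         "restrict to at most 20 systems")
  n_tpl <- 2L^(S - 1L) - 1L
  sys_lab <- matrix(0L, n_tpl, S)
  sys_lab[, 1L] <- 1L
  for (k in seq_len(n_tpl)) {
    code <- k - 1L  # bits over systems 2..S; all-ones code excluded by range
    sys_lab[k, 1L + which(bitwAnd(code, bitwShiftL(1L, 0:(S - 2L))) > 0L)] <- 1L
  }
  sys_idx <- match(partition$labels, partition$systems)
  structure(list(system_labels = sys_lab,
                 node_labels = sys_lab[, sys_idx, drop = FALSE],
                 systems = partition$systems),
            class = "template_set")
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("template_set: %d bipartition templates over %d systems, %d nodes\n",
              nrow(x$system_labels), length(x$systems), ncol(x$node_labels)))
  invisible(x)
}

#' Node-level co-assignment matrix of one template
#'
#' @param labels 0/1 node label vector.
#' @return Binary N x N matrix, 1 where two nodes share a group.
#' @export
template_coassignment <- function(labels) {
  outer(labels, labels, "==") * 1
}

# General normalized mutual information between two label vectors,
# normalized by the arithmetic mean of the entropies.  Either partition
# having zero entropy (a single group) gives NMI 0.
nmi_labels <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b) / length(a)
  pa <- rowSums(tab); pb <- colSums(tab)
  ha <- -sum(ifelse(pa > 0, pa * log(pa), 0))
  hb <- -sum(ifelse(pb > 0, pb * log(pb), 0))
  if (ha == 0 || hb == 0) return(0)
  e <- outer(pa, pb)
  mi <- sum(ifelse(tab > 0, tab * log(tab / e), 0))
  unname(mi / ((ha + hb) / 2))
}

#' Normalized mutual information between two bipartitions
#'
#' Complement-invariant (relabeling either side leaves it unchanged);
#' normalization by the arithmetic mean of the two entropies.  Degenerate
#' single-group partitions give 0.
#'
#' @param a,b 0/1 label vectors of equal length.
#' @return Scalar in `[0, 1]`.
#' @export
nmi_bipartitions <- function(a, b) {
  nmi_labels(as.integer(a), as.integer(b))
}

#' Match patterns to system templates and build weighted templates
#'
#' Each pattern's sign bipartition is matched to the template with maximal
#' NMI (ties to the lowest template index).  The weighted template is the
#' sum of the matched templates' co-assignment matrices, each weighted by
#' the relative frequency with which it was the best match; the z-scored
#' variant standardizes its off-diagonal entries.
#'
#' @param bips P x N matrix of pattern bipartitions.
#' @param templates a `template_set`.
#' @return List with `match` (template index per pattern), `nmi` (its NMI),
#'   `freq` (per-template match frequency, sums to 1), `weighted` and
#'   `weighted_z` node x node matrices.
#' @export
match_to_templates <- function(bips, templates) {
  TL <- templates$node_labels
  n_tpl <- nrow(TL); N <- ncol(TL)
  bips <- as.matrix(bips)
  stopifnot(ncol(bips) == N, nrow(bips) >= 1L)
  # vectorized 2x2 contingencies: n11[t, p] = # nodes labeled 1 by both
  n11 <- TL %*% t(bips)
  t1 <- rowSums(TL); p1 <- rowSums(bips)
  n10 <- t1 - n11
  n01 <- matrix(p1, n_tpl, nrow(bips), byrow = TRUE) - n11
  n00 <- N - n11 - n10 - n01
  plogp <- function(x) ifelse(x > 0, x * log(x), 0)
  hT <- -(plogp(t1 / N) + plogp(1 - t1 / N))
  hP <- -(plogp(p1 / N) + plogp(1 - p1 / N))
  mi <- matrix(0, n_tpl, nrow(bips))
  for (cell in list(list(n11, t1, p1), list(n10, t1, N - p1),
                    list(n01, N - t1, p1), list(n00, N - t1, N - p1))) {
    nij <- cell[[1]] / N
    eij <- outer(cell[[2]] / N, cell[[3]] / N)
    mi <- mi + ifelse(nij > 0 & eij > 0, nij * log(nij / eij), 0)
  }
  hm <- (outer(hT, hP, "+")) / 2
  nmi <- ifelse(hm > 0, mi / hm, 0)
  nmi[hT == 0, ] <- 0
  nmi[, hP == 0] <- 0
  match_idx <- apply(nmi, 2L, which.max)
  best_nmi <- nmi[cbind(match_idx, seq_along(match_idx))]
  freq <- tabulate(match_idx, nbins = n_tpl) / length(match_idx)
  weighted <- matrix(0, N, N)
  for (t in which(freq > 0))
    weighted <- weighted + freq[t] * template_coassignment(TL[t, ])
  off <- upper.tri(weighted) | lower.tri(weighted)
  wz <- weighted
  wz[off] <- (weighted[off] - mean(weighted[off])) / sd(weighted[off])
  diag(wz) <- 0
  list(match = match_idx, nmi = best_nmi, freq = freq,
       weighted = weighted, weighted_z = wz)
}
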