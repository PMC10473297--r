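#' Uniform-null modularity matrix from a concordance matrix
#'
#' The expected weight between any two patterns is the single constant
#' `P_exp = mean of the upper-triangle concordances`; the modularity matrix
#' is `B = C - P_exp` off-diagonal with zero diagonal.  By construction the
#' upper-triangle of `B` sums to zero, so the trivial one-community partition
#' has modularity Q = 0.
#'
#' @param C symmetric concordance matrix (P >= 2).
#' @return Matrix `B` with attribute `p_exp`.
#' @export
modularity_matrix <- function(C) {
  P <- nrow(C)
  stopifnot(P >= 2L, ncol(C) == P)
  p_exp <- mean(C[upper.tri(C)])
  B <- C - p_exp
  diag(B) <- 0
  attr(B, "p_exp") <- p_exp
  attr(B, "meta") <- NULL
  B
}

# canonical labels: consecutive integers in order of first appearance
relabel_first_appearance <- function(lab) {
  match(lab, unique(lab))
}

#' Single Louvain optimization of signed modularity
#'
#' Greedy two-phase Louvain generalized to an arbitrary signed, symmetric
#' modularity matrix: phase one moves nodes (random order) to the community
#' that maximizes the summed within-community weight; phase two aggregates
#' communities into supernodes (within weight becomes a self-loop) and
#' repeats.  Returns a local optimum.
#'
#' @param B modularity matrix (symmetric, zero diagonal).
#' @param seed integer RNG seed for the node visit order.
#' @return Integer label vector (1-based, order of first appearance).
#' @export
louvain_partition <- function(B, seed = 1L) {
  relabel_first_appearance(cpp_louvain(unclass(B), as.integer(seed)))
}

#' Partition modularity
#'
#' `Q = sum_{i != j, same community} B_ij` (ordered-pair convention).
#'
#' @param B modularity matrix.
#' @param labels integer community labels.
#' @return Scalar modularity.
#' @export
partition_modularity <- function(B, labels) {
  sum(vapply(unique(labels), function(c)
    community_contribution(B, labels, c), numeric(1)))
}

#' Modularity contribution of one community
#'
#' `q_c = sum_{i in c, j in c, i != j} B_ij`, summed over ordered pairs
#' (each unordered pair counted twice; halving rescales observed and null
#' values identically, so permutation p-values are unaffected).
#'
#' @param B modularity matrix.
#' @param labels integer label vector.
#' @param c community id.
#' @return Scalar contribution `q_c`.
#' @export
community_contribution <- function(B, labels, c) {
  mem <- which(labels == c)
  if (length(mem) < 2L) return(0)
  sum(B[mem, mem])
}

#' Consensus partition over a Louvain ensemble
#'
#' Runs Louvain `n_runs` times from random initial conditions.  If runs
#' disagree, their co-classification frequency matrix `D` is compared with
#' the expected co-classification under random relabelling of each run
#' (`d0`), and the ensemble is re-run on `D - d0`; iterate until all runs
#' return the same partition.
#'
#' @param B modularity matrix.
#' @param n_runs ensemble size (default 1000).
#' @param seed master seed; the procedure is deterministic given it.
#' @param max_iter consensus iteration cap (default 50); on hitting it, the
#'   modal partition is returned with a warning.
#' @return Integer label vector (order of first appearance).
#' @export
consensus_partition <- function(B, n_runs = 1000, seed = 1L, max_iter = 50L) {
  stopifnot(n_runs >= 2L)
  Bcur <- unclass(B)
  for (it in seq_len(max_iter)) {
    L <- cpp_louvain_ensemble(Bcur, as.integer(n_runs),
                              derive_seed(seed, it))
    canon <- apply(L, 2L, relabel_first_appearance)
    if (all(canon == canon[, 1L]))
      return(as.integer(canon[, 1L]))
    cc <- cpp_coclassification(L)
    Bcur <- cc$D - cc$d0
    diag(Bcur) <- 0
  }
  warning("consensus did not converge in ", max_iter,
          " iterations; returning modal partition")
  key <- apply(canon, 2L, paste, collapse = ",")
  as.integer(canon[, which.max(ave(seq_along(key), key, FUN = length))])
}

#' Permutation test of community contributions
#'
#' Null: community sizes are preserved but patterns are assigned to
#' communities uniformly at random (`n_perm` repetitions).  The p-value of a
#' community is the fraction of permutations whose null `q_c` is at least
#' the observed value (ties count as exceeding; no pseudocount).
#'
#' @param B modularity matrix.
#' @param labels consensus labels.
#' @param n_perm permutations (default 10000).
#' @param seed RNG seed.
#' @return data.frame with `community`, `size`, `q`, `p`.
#' @export
significance_test <- function(B, labels, n_perm = 10000, seed = 1L) {
  ids <- sort(unique(labels))
  sizes <- vapply(ids, function(c) sum(labels == c), integer(1))
  q <- vapply(ids, function(c) community_contribution(B, labels, c),
              numeric(1))
  null <- cpp_perm_qc(unclass(B), sizes, as.integer(n_perm),
                      as.integer(seed))
  # floating-point ties (e.g. the all-inclusive community, where every
  # permutation reproduces q = 0 up to summation order) must count as
  # exceeding, so compare with a relative tolerance
  p <- vapply(seq_along(ids), function(k) {
    tol <- 1e-8 * max(abs(q[k]), 1)
    mean(null[, k] >= q[k] - tol)
  }, numeric(1))
  data.frame(community = ids, size = sizes, q = q, p = p)
}

#' Recursive significance-gated hierarchical clustering
#'
#' Level 1 is the trivial all-inclusive root.  At each level every surviving
#' community's concordance submatrix is re-centred (expected weight
#' recomputed on the submatrix), consensus-partitioned, and its child
#' communities are tested against the size-preserving permutation null.
#' Children are propagated only if `p < alpha`, they contain at least
#' `min_size` patterns, and they draw on at least `min_scans` distinct scan
#' sessions.  The recursion stops at the first level with no surviving
#' community; that empty level is recorded, so a structureless input yields
#' exactly two levels (root + empty).
#'
#' @param C concordance matrix.
#' @param scan_ids character vector of per-pattern scan identifiers (defaults
#'   to the `meta` attribute of `C` when present).
#' @param alpha per-community significance level (default 0.05, uncorrected).
#' @param min_size minimum community size (default 5).
#' @param min_scans minimum number of distinct scans represented (default 2).
#' @param n_runs Louvain ensemble size (default 1000).
#' @param n_perm permutations for the contribution test (default 10000).
#' @param seed master seed; the full result is deterministic given it.
#' @return A `cofluct_hierarchy` object: `levels` (list of per-pattern label
#'   vectors, 0 = pruned), `communities` (one row per candidate community:
#'   level, id, parent, size, q, p, n_scans, kept), `members` (list of index
#'   vectors by community id), `n_levels`, `params`.
#' @export
recursive_cluster <- function(C, scan_ids = NULL, alpha = 0.05,
                              min_size = 5L, min_scans = 2L,
                              n_runs = 1000, n_perm = 10000, seed = 1L) {
  P <- nrow(C)
  if (is.null(scan_ids)) {
    meta <- attr(C, "meta")
    scan_ids <- if (!is.null(meta)) meta$scan_id else rep("scan1", P)
  }
  stopifnot(length(scan_ids) == P, P >= min_size)
  levels <- list(rep(1L, P))
  comms <- data.frame(level = 1L, id = 1L, parent = NA_integer_, size = P,
                      q = 0, p = NA_real_,
                      n_scans = length(unique(scan_ids)), kept = TRUE)
  members <- list(`1` = seq_len(P))
  active <- list(list(id = 1L, members = seq_len(P)))
  next_id <- 1L; node <- 0L
  repeat {
    newlab <- rep(0L, P)
    new_active <- list()
    for (parent in active) {
      node <- node + 1L
      mem <- parent$members
      Bsub <- modularity_matrix(C[mem, mem, drop = FALSE])
      lab <- consensus_partition(Bsub, n_runs = n_runs,
                                 seed = derive_seed(seed, 2L * node))
      sig <- significance_test(Bsub, lab, n_perm = n_perm,
                               seed = derive_seed(seed, 2L * node + 1L))
      for (k in seq_len(nrow(sig))) {
        cm <- mem[lab == sig$community[k]]
        n_sc <- length(unique(scan_ids[cm]))
        keep <- sig$p[k] < alpha && length(cm) >= min_size &&
          n_sc >= min_scans
        next_id <- next_id + 1L
        comms <- rbind(comms, data.frame(
          level = length(levels) + 1L, id = next_id, parent = parent$id,
          size = length(cm), q = sig$q[k], p = sig$p[k], n_scans = n_sc,
          kept = keep))
        members[[as.character(next_id)]] <- cm
        if (keep) {
          newlab[cm] <- next_id
          new_active[[length(new_active) + 1L]] <-
            list(id = next_id, members = cm)
        }
      }
    }
    levels[[length(levels) + 1L]] <- newlab
    active <- new_active
    if (length(active) == 0L) break
  }
  structure(list(levels = levels, communities = comms, members = members,
                 n_levels = length(levels), scan_ids = scan_ids,
                 params = list(alpha = alpha, min_size = min_size,
                               min_scans = min_scans, n_runs = n_runs,
                               n_perm = n_perm, seed = seed)),
            class = "cofluct_hierarchy")
}

#' @export
print.cofluct_hierarchy <- function(x, ...) {
  kept <- x$communities[x$communities$kept, ]
  cat(sprintf("cofluct_hierarchy: %d levels over %d patterns\n",
              x$n_levels, length(x$levels[[1]])))
  for (l in seq_len(x$n_levels))
    cat(sprintf("  level %d: %d communities\n", l,
                sum(kept$level == l)))
  invisible(x)
}

#' Co-assignment probabilities across hierarchy levels
#'
#' Entry (i, j) is the fraction of levels — among those in which both i and
#' j are still assigned — where they share a community.
#'
#' @param H a `cofluct_hierarchy`.
#' @return Symmetric P x P matrix in `[0, 1]`.
#' @export
hierarchy_coassignment <- function(H) {
  P <- length(H$levels[[1]])
  num <- matrix(0, P, P); den <- matrix(0, P, P)
  for (lab in H$levels) {
    a <- lab > 0L
    both <- outer(a, a, "&")
    den <- den + both
    same <- outer(lab, lab, "==") & both
    num <- num + same
  }
  out <- ifelse(den > 0, num / den, 0)
  out
}

#' Per-pattern hierarchical depth
#'
#' Number of levels in which a pattern remains assigned before being pruned
#' (the root counts, so depth >= 1 everywhere).
#'
#' @param H a `cofluct_hierarchy`.
#' @return Integer vector of length P.
#' @export
hierarchical_depth <- function(H) {
  Reduce(`+`, lapply(H$levels, function(lab) as.integer(lab > 0L)))
}
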