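# Independent oracles and small fixture builders used across test files.

# Brute-force Lin's concordance straight from the formula (population moments)
oracle_lin <- function(x, y) {
  n <- length(x)
  covp <- sum((x - mean(x)) * (y - mean(y))) / n
  varp <- function(v) sum((v - mean(v))^2) / n
  2 * covp / (varp(x) + varp(y) + (mean(x) - mean(y))^2)
}

# All set partitions of n elements as label vectors (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(labels, k) {
    if (length(labels) == n) { out[[length(out) + 1L]] <<- labels; return() }
    for (c in seq_len(k + 1L)) rec(c(labels, c), max(k, c))
  }
  rec(integer(0), 0L)
  out
}

# Exhaustive maximum of Q = sum_{i!=j, same comm} B_ij over all partitions
oracle_max_modularity <- function(B) {
  best <- -Inf
  for (lab in all_partitions(nrow(B))) {
    q <- sum(vapply(unique(lab), function(c) {
      m <- which(lab == c)
      if (length(m) < 2) 0 else sum(B[m, m])
    }, numeric(1)))
    if (q > best) best <- q
  }
  best
}

# Brute-force bipartition templates: all 2^S 0/1 assignments, drop trivial,
# dedup complements
oracle_templates <- function(S) {
  seen <- character(0)
  count <- 0L
  for (code in 0:(2^S - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(S)]
    if (all(bits == 0L) || all(bits == 1L)) next
    canon <- if (bits[1] == 1L) bits else 1L - bits
    key <- paste(canon, collapse = "")
    if (!(key %in% seen)) { seen <- c(seen, key); count <- count + 1L }
  }
  count
}

# random small modularity matrix from the planted-partition family the
# clustering targets: 1-3 blocks of random sizes, within +0.5, between -0.2,
# symmetric gaussian noise
random_small_B <- function(n, seed) {
  set.seed(seed)
  K <- sample(1:3, 1)
  lab <- sort(sample(seq_len(K), n, replace = TRUE))
  B <- matrix(-0.2, n, n)
  for (k in seq_len(K)) B[lab == k, lab == k] <- 0.5
  E <- matrix(rnorm(n^2, sd = 0.2), n, n)
  B <- B + (E + t(E)) / 2
  diag(B) <- 0
  B
}

# planted block modularity matrix: K blocks of size bs, within w, between b,
# gaussian noise sd
planted_B <- function(K, bs, within = 0.5, between = -0.2, noise = 0.1,
                      seed = 1) {
  set.seed(seed)
  n <- K * bs
  lab <- rep(seq_len(K), each = bs)
  B <- matrix(between, n, n)
  for (k in seq_len(K)) B[lab == k, lab == k] <- within
  E <- matrix(rnorm(n * n, sd = noise), n, n)
  B <- B + (E + t(E)) / 2
  diag(B) <- 0
  list(B = B, labels = lab)
}

# tiny two-parcel-plus scan with a hand-made censor mask
make_ts <- function(X, tr = 1, censor = NULL, scan_id = "s1") {
  parcel_ts(as.matrix(X), tr = tr, censor = censor, scan_id = scan_id)
}

# match detected peak patterns to planted events; returns data.frame with
# pattern index and planted state / super-state (NA for unplanted peaks)
match_planted <- function(patterns, truth) {
  key <- paste(patterns$meta$scan_id, patterns$meta$frame + 1L)
  ekey <- paste(truth$events$scan_id, truth$events$frame)
  idx <- match(key, ekey)
  data.frame(pattern = seq_along(key),
             state = truth$events$state[idx],
             super = truth$events$super_state[idx])
}

# small pattern fixture with prescribed peak RMS values (2 above, 1.2 mid,
# 0.5 below the null distributions used in tests)
new_pat_fixture <- function(rms = c(2, 1.2, 0.5)) {
  set.seed(99)
  E <- matrix(rnorm(length(rms) * 10), length(rms), 10)
  meta <- data.frame(scan_id = "s1", frame = seq_along(rms) - 1L, rms = rms,
                     relative_rms = rms,
                     amplitude_class = rep("unclassified", length(rms)),
                     stringsAsFactors = FALSE)
  cofluct:::new_patterns(E, meta, 5L)
}

nmi_oracle <- function(a, b) {
  # plain contingency NMI, arithmetic-mean normalization
  tab <- table(a, b) / length(a)
  pa <- rowSums(tab); pb <- colSums(tab)
  H <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  mi <- 0
  for (i in seq_along(pa)) for (j in seq_along(pb))
    if (tab[i, j] > 0) mi <- mi + tab[i, j] * log(tab[i, j] / (pa[i] * pb[j]))
  if (H(pa) == 0 || H(pb) == 0) 0 else unname(mi / ((H(pa) + H(pb)) / 2))
}
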