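---
title: "Methods: peak co-fluctuation patterns and their multiscale clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peak co-fluctuation patterns and their multiscale clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cofluct)
```

## The model in brief

Functional connectivity (FC) between two regional signals is their Pearson
correlation, which — once each parcel's time series is z-scored — is the
*temporal average of instantaneous co-fluctuation*:

$$ r_{ij} = \frac{1}{T-1}\sum_t z_i(t)\,z_j(t). $$

Omitting the sum yields the **edge time series** $r_{ij}(t) = z_i(t) z_j(t)$,
an exact framewise decomposition of FC: averaging the edge time series
recovers every correlation to machine precision (this identity is enforced
by a test at $10^{-10}$ on $100 \times 500$ random data, and is why
z-scoring uses the *sample* standard deviation, denominator $n-1$).

A single frame's full edge vector is the upper triangle of the rank-1 outer
product $z(t)z(t)^\top$: at any instant the network can only express one
"activity mode" and its sign structure. The global co-fluctuation amplitude
is the RMS over edges,

$$ R(t) = \sqrt{\tfrac{1}{|E|}\sum_{i<j} r_{ij}(t)^2}, $$

computed in closed form per frame via
$\sum_{i<j}(z_i z_j)^2 = ((\sum z^2)^2 - \sum z^4)/2$, so the edge × time
matrix is never materialized (memory stays $O(N^2)$ per frame). Any
monotone variant of $R(t)$ (sum of squares, with or without the root)
preserves peak *locations*; the prominence threshold default is calibrated
to the sqrt-mean scale, and `rms_series(mode = "sumsq")` exposes the raw
sum of squares.

## Peak extraction funnel

1. **Censoring**: frames flagged high-motion are dropped, plus all frames
   within `pad_frames = 2` TRs on either side (the symmetric reading of
   "within two TRs"; the pad is configurable, so a forward-only policy can
   be emulated upstream). Surviving contiguous runs shorter than
   `min_run = 5` frames are discarded. All subsequent segmentation is
   per-run; z-scoring moments are pooled over all retained frames of the
   scan.
2. **Segmentation**: strict local minima of $R(t)$ are troughs; run
   endpoints act as additional boundaries so censoring-induced runs do not
   discard valid interior peaks. Each trough-to-trough segment contains
   exactly one peak (leftmost frame of a plateau).
3. **Prominence**: relative RMS = peak height minus the larger neighboring
   trough; peaks with relative RMS ≤ `min_relative_rms = 0.25` are dropped.
   Peaks at run boundaries have zero prominence by construction and die
   here.
4. **Separation**: among peaks closer than
   `ceiling(min_separation_s / tr)` frames (default 10 s), the greater
   relative RMS wins, greedily in descending prominence with ties broken by
   the earlier frame.

Only the single peak frame is extracted per segment — segment averages would
conflate estimation precision with segment duration.

Peak amplitude classes (`high` / `ns` / `low`) compare each peak's RMS with
the 97.5th / 2.5th percentiles of the peak-RMS distribution obtained by
running the identical funnel on circular-shift surrogates. The reference
text defers the exact rule to prior work, so the percentile rule and its
cutoffs are explicit arguments.

## Lin's concordance

Pattern similarity is Lin's concordance,

$$ C_{xy} = \frac{2\,\mathrm{Cov}(x,y)}
   {\mathrm{Var}(x)+\mathrm{Var}(y)+(\mu_x-\mu_y)^2}, $$

with population ($1/n$) moments, per the measure's original definition (the
equality-with-correlation property when moments match holds under either
convention). Unlike Pearson correlation it penalizes amplitude mismatch:
$|C| \le |r|$ always, with equality iff means and variances agree — both
properties are tested against a brute-force evaluation of the formula.
Degenerate conventions: two equal constant vectors give 1, two unequal
constant vectors give 0.

## Recursive, significance-gated modularity maximization

For each community's concordance submatrix the expected edge weight is the
single constant $P = \langle C_{ij} \rangle_{i<j}$ recomputed on that
submatrix, so the modularity matrix $B = C - P$ has zero-sum upper triangle
at every recursion node and the trivial one-community partition always has
$Q = 0$. Community contributions are counted over ordered pairs
($q_c = \sum_{i \ne j \in c} B_{ij}$, so each unordered pair counts twice);
halving would rescale observed and null values identically, leaving
p-values untouched.

The optimizer is a bespoke signed-matrix Louvain written in C++: greedy
local moves in random order, with the signed-case option of splitting off
into an empty community when a node's net attachment is negative,
alternating with multilevel aggregation until $Q$ stops improving. It is run
`n_runs = 1000` times from random initial conditions; if runs disagree,
their co-classification frequency matrix minus its label-permutation
expectation is re-clustered by the same ensemble until all runs agree
(regenerated, not recycled, at each iteration; a 50-iteration cap returns
the modal partition with a warning). On ≤ 8-node planted-partition matrices
the consensus matches exhaustive search; on *unstructured* Gaussian
matrices it matches only ~90% of the time, converging to the largest-basin
local optimum — a documented property of the Louvain family, not a defect
the package hides.

Each consensus community is tested against a null that preserves community
sizes but reassigns patterns at random (`n_perm = 10000`); the p-value is
the raw fraction of null $q_c \ge$ observed (no pseudocount; ties count as
exceeding, with a small relative tolerance so floating-point reordering of
an exact tie — e.g. the all-inclusive community, where every permutation
reproduces $q = 0$ — does not break it). Communities survive to the next
level only if $p < \alpha = 0.05$ (uncorrected, per-community), they have
at least `min_size = 5` members, and they draw on at least `min_scans = 2`
distinct scan sessions. Level 1 is the trivial root; the first level with
no survivors is recorded, so a structureless input yields exactly two
levels. Pruned patterns never reappear deeper, and children partition their
parent exclusively, giving an unambiguous dendrogram.

### What the null-calibration test does and does not establish

The reference null experiment applies the pipeline to circular-shift
surrogates of a **single scan session**, and the package reproduces its
every-run result (exactly two levels). Two gates contribute: the
significance test, and — decisively in the single-session design — the
`min_scans` rule, which no community built from one session can satisfy.
With *multi-session* surrogates the recursion does **not** reliably stop at
level 2: the permutation null reassigns patterns under the *observed*
partition and therefore does not account for the optimizer having selected
the partition on the same data, so optimized $q_c$ on pure-noise
concordance sits deep in the null tail. Users clustering data where
scan-diversity pruning cannot bite should treat deep levels with
correspondingly more caution (or verify against their own surrogates).

## Downstream characterization

* **Centroids** are element-wise means of member edge vectors, reshaped to
  symmetric matrices with zero diagonal (self-pairs never exist).
* **Leading eigenmode**: co-fluctuation matrices are indefinite, so the
  mode is the eigenvector of the largest-|eigenvalue| and variance
  explained is $|\lambda_1| / \sum_k |\lambda_k|$ (the normalization is a
  package choice; a single-frame pattern gives exactly 1 under it). The
  sign is fixed so the largest-magnitude element is positive.
* **Bipartitions**: each frame splits parcels by activity sign (zeros to
  the "below" group — a measure-zero, deterministic convention);
  $r_{ij}(t) > 0$ iff $i, j$ share a side. System templates enumerate all
  $2^{S-1}-1$ two-group partitions of the $S$ systems up to complement
  (canonical form: the first system's group is labeled 1; 8,191 for
  S = 14). Template matching uses normalized mutual information with
  arithmetic-mean entropy normalization (the variant is configurable in
  principle; degenerate single-group partitions score 0). The weighted
  template sums matched templates' co-assignment matrices by match
  frequency; its z-scored variant standardizes off-diagonal entries.
* **Hierarchical depth** counts levels survived (root included);
  `depth_fc_curves()` correlates mean patterns with static FC selecting by
  exact depth, depth ≥ level, or depth ≤ level.
* **Data requirement**: cluster labels come from the full-data hierarchy
  and are held fixed; scans are repeatedly split in half, one half's
  centroids are rebuilt scan-by-scan in random order and correlated with
  the other half's reference centroids. Cluster-absent increments are
  missing values, never zeros or interpolations. Reindexing the curves by
  cumulative sample count (linear interpolation onto the overlapping
  sample range) collapses frequency differences between clusters.

## The synthetic generator

`generate_state_switching_data()` emulates exactly the statistical
structure the pipeline assumes: i.i.d. Gaussian baseline noise punctured by
single-frame events where activity aligns with one of K recurring
system-block sign modes, so event frames are noisy rank-1 co-fluctuation
patterns. Defaults state a desk-scale dense-sampling world: 10 scans ×
600 frames at TR 1.16 s, 100 parcels in 10 systems, K = 3 states, 6 events
per state per scan (≈ 18 peaks per scan, comparable to the ~19 per session
of a dense-sampling study), amplitude 3 against noise sd 0.5. Event counts
are Poisson per scan and state; frames are placed with a minimum mutual
spacing just above the 10-s separation window so planted events land in
distinct segments (events beyond spacing capacity are dropped — only
reachable when Poisson counts spike). Two-level planting derives sub-modes
from a super-mode by adding an orthogonal sign perturbation (default
magnitude 0.6, putting within-sub > within-super > between concordance).
The split-half analysis simulation lowers the SNR (amplitude 2, noise 1) so
that convergence is visibly incomplete after one scan and the curves have
something to collapse.

What the generator does **not** emulate: hemodynamic autocorrelation,
anatomically constrained dynamics, multi-frame events, amplitude-dependent
censoring. A green recovery test therefore establishes correctness of the
machinery on data satisfying the model's assumptions, not performance on
real BOLD.

Circular-shift surrogates rotate each parcel's series by an independent
uniform offset in $[1, T-1]$, exactly preserving each marginal value
multiset while destroying cross-parcel correlation; censor masks are left
unshifted.

## Numerical and reproducibility choices

* All randomized stages take a seed; a master seed fans out to stage seeds
  by a fixed affine map kept below $2^{31}$. Identical seeds give identical
  hierarchies (tested).
* The C++ cores use their own `std::mt19937` streams, so results do not
  depend on R's global RNG state; R-level generators save and restore
  `.Random.seed`.
* Frame indices are 0-based half-open externally (run table, pattern
  metadata) and 1-based internally in R code; segment tables store 1-based
  row indices into the scan.
* Peak ties: plateau maxima take the leftmost frame; the separation filter
  breaks prominence ties by the earlier frame.

## Known limitations

* The permutation significance gate is anti-conservative with respect to
  optimizer selection (see the null-calibration section); scan-diversity
  pruning is the robust guard.
* Consensus is not an exact maximizer on structureless inputs (~90% oracle
  agreement there, 100% on structured families).
* HDF5 containers are not supported (no HDF5 binding in the target
  environment); I/O is delimited text plus JSON manifests.
* Only two-group (bipartition) templates are enumerated, and template
  enumeration refuses S > 20 systems.
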