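#' Configuration for the state-switching synthetic generator
#'
#' The generator emulates the statistical structure the pipeline assumes:
#' a noise floor of independent parcel activity, punctured by brief
#' single-frame events in which activity aligns with one of K recurring
#' mode vectors (so the event frame's co-fluctuation pattern is a noisy
#' rank-1 outer product).  Modes are system-block sign patterns; an optional
#' two-level hierarchy derives sub-modes from super-modes by adding an
#' orthogonal sign perturbation of magnitude `hier_perturbation`, which
#' controls the parent-child pattern correlation.
#'
#' Defaults mirror a dense-sampling resting-state study at desk scale:
#' 10 scans of 600 frames (TR 1.16 s), 100 parcels in 10 systems, 3 states,
#' 6 events per state per scan (about 18 peaks per scan), event amplitude 3
#' over noise sd 0.5.
#'
#' @param n_parcels,n_frames,n_scans,tr dimensions and sampling rate.
#' @param n_states number of planted states K (ignored if `hier` given).
#' @param events_per_scan events per state per scan; scalar or length-K.
#' @param amplitude mean event amplitude (activity units per mode element).
#' @param amplitude_jitter sd of per-event amplitude jitter.
#' @param noise_sd baseline/additive noise sd.
#' @param n_systems number of parcel blocks used to draw modes.
#' @param hier optional list `(n_super, subs_per_super, perturbation)` for
#'   two-level planting; then K = n_super * subs_per_super.
#' @param poisson_events draw per-scan event counts as Poisson with mean
#'   `events_per_scan` (default) instead of fixed rounded counts.
#' @param censor_fraction target fraction of censored frames.
#' @param censor_burst_mean mean censored-burst length in frames.
#' @param modes optional K x N matrix of custom mode vectors.
#' @param seed master seed.
#' @return Validated config list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_parcels = 100L, n_frames = 600L,
                             n_scans = 10L, tr = 1.16, n_states = 3L,
                             events_per_scan = 6L, amplitude = 3,
                             amplitude_jitter = 0, noise_sd = 0.5,
                             n_systems = 10L, hier = NULL,
                             poisson_events = TRUE,
                             censor_fraction = 0, censor_burst_mean = 4,
                             modes = NULL, seed = 1L) {
  if (!is.null(hier)) {
    stopifnot(is.list(hier), hier$n_super >= 1L, hier$subs_per_super >= 1L)
    hier$perturbation <- hier$perturbation %||% 0.6
    n_states <- hier$n_super * hier$subs_per_super
  }
  stopifnot(n_parcels >= 2L, n_frames >= 10L, n_scans >= 1L, tr > 0,
            n_states >= 1L, all(events_per_scan >= 0),
            amplitude > 0, noise_sd >= 0,
            censor_fraction >= 0, censor_fraction < 1)
  if (length(events_per_scan) == 1L)
    events_per_scan <- rep(events_per_scan, n_states)
  if (length(events_per_scan) != n_states)
    stop("events_per_scan must be scalar or length n_states")
  if (!is.null(modes)) {
    modes <- as.matrix(modes)
    if (nrow(modes) != n_states || ncol(modes) != n_parcels)
      stop("modes must be n_states x n_parcels")
    if (any(apply(modes, 1L, sd) == 0)) stop("degenerate mode vector")
  }
  structure(list(n_parcels = as.integer(n_parcels),
                 n_frames = as.integer(n_frames),
                 n_scans = as.integer(n_scans), tr = tr,
                 n_states = as.integer(n_states),
                 events_per_scan = as.numeric(events_per_scan),
                 amplitude = amplitude, amplitude_jitter = amplitude_jitter,
                 noise_sd = noise_sd, n_systems = as.integer(n_systems),
                 hier = hier, poisson_events = isTRUE(poisson_events),
                 censor_fraction = censor_fraction,
                 censor_burst_mean = censor_burst_mean, modes = modes,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# draw system-block sign modes (and the super-state map if hierarchical)
make_state_modes <- function(cfg) {
  N <- cfg$n_parcels
  sys <- sort(rep(seq_len(cfg$n_systems), length.out = N))
  rand_signs <- function() {
    s <- sample(c(-1, 1), cfg$n_systems, replace = TRUE)
    if (length(unique(s)) == 1L) s[sample(cfg$n_systems, 1L)] <- -s[1L]
    s
  }
  if (is.null(cfg$hier)) {
    modes <- t(vapply(seq_len(cfg$n_states),
                      function(k) rand_signs()[sys], numeric(N)))
    super <- seq_len(cfg$n_states)
  } else {
    modes <- matrix(0, cfg$n_states, N)
    super <- integer(cfg$n_states)
    k <- 0L
    for (s in seq_len(cfg$hier$n_super)) {
      base <- rand_signs()
      for (j in seq_len(cfg$hier$subs_per_super)) {
        k <- k + 1L
        pert <- sample(c(-1, 1), cfg$n_systems, replace = TRUE)
        modes[k, ] <- (base + cfg$hier$perturbation * pert)[sys]
        super[k] <- s
      }
    }
  }
  list(modes = modes, super = super, systems = sys)
}

#' Generate multi-scan state-switching parcel time series
#'
#' Baseline frames are i.i.d. Gaussian noise; at each planted event frame
#' the activity is `amplitude * mode_k + noise`.  Event frames are placed
#' with a minimum mutual spacing of `ceiling(10 / tr) + 2` frames so planted
#' events land in distinct trough-to-trough segments and survive the
#' separation filter; counts per state follow `events_per_scan`.
#'
#' @param cfg a [synthetic_config()].
#' @return List with `scans` (list of [parcel_ts()]) and `truth` (list:
#'   `events` data.frame with scan_id, frame (1-based), state, super_state,
#'   amplitude; `modes`; `super`; `systems`; `planted_fc` implied
#'   correlation matrix).
#' @export
generate_state_switching_data <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  ms <- if (is.null(cfg$modes)) make_state_modes(cfg)
        else list(modes = cfg$modes, super = seq_len(cfg$n_states),
                  systems = sort(rep(seq_len(cfg$n_systems),
                                     length.out = cfg$n_parcels)))
  N <- cfg$n_parcels; T <- cfg$n_frames
  min_gap <- ceiling(10 / cfg$tr) + 2L
  scans <- vector("list", cfg$n_scans)
  events <- list()
  for (s in seq_len(cfg$n_scans)) {
    X <- matrix(rnorm(T * N, sd = cfg$noise_sd), T, N)
    n_ev <- if (cfg$poisson_events) rpois(cfg$n_states, cfg$events_per_scan)
            else as.integer(round(cfg$events_per_scan))
    total <- sum(n_ev)
    # greedy spaced placement of event frames
    cand <- sample((min_gap + 1L):(T - min_gap))
    placed <- integer(0)
    for (f in cand) {
      if (length(placed) == total) break
      if (!any(abs(placed - f) < min_gap)) placed <- c(placed, f)
    }
    # events beyond the spacing capacity of the scan are dropped (only
    # reachable when Poisson counts spike near capacity)
    states <- sample(rep(seq_len(cfg$n_states), n_ev))
    if (length(placed) < total) {
      total <- length(placed)
      states <- states[seq_len(total)]
    }
    amp <- pmax(cfg$amplitude + rnorm(total, 0, cfg$amplitude_jitter),
                cfg$amplitude / 10)
    for (e in seq_len(total))
      X[placed[e], ] <- amp[e] * ms$modes[states[e], ] +
        rnorm(N, sd = cfg$noise_sd)
    censor <- if (cfg$censor_fraction > 0)
      generate_censor_mask(T, cfg$censor_fraction, cfg$censor_burst_mean,
                           seed = derive_seed(cfg$seed, s))
      else rep(1L, T)
    sid <- sprintf("scan%02d", s)
    scans[[s]] <- parcel_ts(X, tr = cfg$tr, censor = censor, scan_id = sid)
    events[[s]] <- data.frame(scan_id = sid, frame = placed,
                              state = states, super_state = ms$super[states],
                              amplitude = amp)
  }
  # implied covariance: noise + per-state event mixtures (expected rates)
  rate <- cfg$events_per_scan / T
  cov <- diag(cfg$noise_sd^2, N)
  for (k in seq_len(cfg$n_states))
    cov <- cov + rate[k] * cfg$amplitude^2 * tcrossprod(ms$modes[k, ])
  planted_fc <- cov / tcrossprod(sqrt(diag(cov)))
  list(scans = scans,
       truth = list(events = do.call(rbind, events), modes = ms$modes,
                    super = ms$super, systems = ms$systems,
                    planted_fc = planted_fc))
}

#' Circular-shift surrogate of a scan
#'
#' Rotates each parcel's series by an independent uniform offset in
#' `[1, T-1]`, exactly preserving each parcel's value multiset (hence all
#' marginal moments) while destroying cross-parcel correlation.  The censor
#' mask is left unshifted.
#'
#' @param ts a [parcel_ts()].
#' @param seed RNG seed.
#' @return A new [parcel_ts()].
#' @export
circular_shift_surrogate <- function(ts, seed = 1L) {
  stopifnot(inherits(ts, "parcel_ts"))
  T <- nrow(ts$data)
  if (T < 2L) stop("need at least 2 frames")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  offs <- sample(T - 1L, ncol(ts$data), replace = TRUE)
  X <- ts$data
  for (j in seq_len(ncol(X))) {
    o <- offs[j]
    X[, j] <- c(ts$data[(T - o + 1L):T, j], ts$data[seq_len(T - o), j])
  }
  parcel_ts(X, ts$tr, ts$censor, paste0(ts$scan_id, "_shift"), ts$parcel_ids)
}

#' Generate a bursty censor mask
#'
#' Censored frames arrive in geometric-length bursts (mean
#' `burst_length_mean`), separated by geometric usable stretches sized so
#' the long-run censored fraction matches the target.
#'
#' @param T number of frames.
#' @param censored_fraction target fraction in `[0, 1)`.
#' @param burst_length_mean mean burst length in frames.
#' @param seed RNG seed.
#' @return Integer 0/1 vector of length `T` (1 = usable).
#' @export
generate_censor_mask <- function(T, censored_fraction, burst_length_mean = 4,
                                 seed = 1L) {
  stopifnot(censored_fraction >= 0, censored_fraction < 1)
  if (censored_fraction == 0) return(rep(1L, T))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  mean_good <- burst_length_mean * (1 - censored_fraction) / censored_fraction
  mask <- integer(0)
  good <- runif(1) > censored_fraction
  while (length(mask) < T) {
    len <- if (good) rgeom(1, min(1, 1 / mean_good)) + 1L
           else rgeom(1, min(1, 1 / burst_length_mean)) + 1L
    mask <- c(mask, rep(if (good) 1L else 0L, len))
    good <- !good
  }
  mask[seq_len(T)]
}

#' Null peak-RMS distribution from circular-shift surrogates
#'
#' Runs the full peak-extraction funnel on circular-shift surrogates of each
#' scan and pools the surviving peak RMS values; used to calibrate
#' high/low-amplitude classification.
#'
#' @param scans list of [parcel_ts()].
#' @param n_surrogates surrogates per scan (default 1).
#' @param seed RNG seed.
#' @param ... passed to [scan_peak_patterns()].
#' @return Numeric vector of surrogate peak RMS values.
#' @export
surrogate_peak_rms <- function(scans, n_surrogates = 1L, seed = 1L, ...) {
  out <- numeric(0)
  k <- 0L
  for (ts in scans) for (r in seq_len(n_surrogates)) {
    k <- k + 1L
    sur <- circular_shift_surrogate(ts, seed = derive_seed(seed, k))
    out <- c(out, scan_peak_patterns(sur, ...)$meta$rms)
  }
  out
}
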