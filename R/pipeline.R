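#' Pipeline run configuration
#'
#' All stage parameters in one serializable object.  Defaults are the
#' method's canonical values: censor padding 2 frames, minimum run 5
#' frames, prominence threshold 0.25, 10-s peak separation, 1000 Louvain
#' runs, 10000 permutations, alpha 0.05, minimum community size 5, at least
#' 2 distinct scans per community.
#'
#' @param pad_frames,min_run run segmentation parameters.
#' @param min_relative_rms,min_separation_s,rms_mode peak detection.
#' @param hi_pct,lo_pct,n_surrogates amplitude classification.
#' @param alpha,min_size,min_scans,n_runs,n_perm hierarchical clustering.
#' @param simulate `NULL`, or a list of [synthetic_config()] arguments used
#'   to generate input data.
#' @param seed master seed; all stage seeds are derived from it.
#' @param out_dir optional output directory.
#' @return List of class `run_config`.
#' @export
run_config <- function(pad_frames = 2L, min_run = 5L,
                       min_relative_rms = 0.25, min_separation_s = 10,
                       rms_mode = "rms", hi_pct = 97.5, lo_pct = 2.5,
                       n_surrogates = 1L, alpha = 0.05, min_size = 5L,
                       min_scans = 2L, n_runs = 1000L, n_perm = 10000L,
                       simulate = NULL, seed = 1L, out_dir = NULL) {
  structure(list(pad_frames = as.integer(pad_frames),
                 min_run = as.integer(min_run),
                 min_relative_rms = min_relative_rms,
                 min_separation_s = min_separation_s, rms_mode = rms_mode,
                 hi_pct = hi_pct, lo_pct = lo_pct,
                 n_surrogates = as.integer(n_surrogates),
                 alpha = alpha, min_size = as.integer(min_size),
                 min_scans = as.integer(min_scans),
                 n_runs = as.integer(n_runs), n_perm = as.integer(n_perm),
                 simulate = simulate, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Write / read a run configuration (lossless JSON round trip)
#'
#' @param config a [run_config()].
#' @param path JSON file path.
#' @return `read_run_config` returns the reconstructed [run_config()].
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x)
}

#' Run the full analysis pipeline
#'
#' Simulate (or ingest) -> peak extraction funnel -> amplitude
#' classification against circular-shift surrogates -> concordance ->
#' recursive hierarchical clustering -> characterization.  Per-stage counts
#' (frames censored, candidate segments, peaks surviving the prominence and
#' separation filters) are collected in a funnel log; they are
#' non-increasing across filters.
#'
#' @param config a [run_config()].
#' @param scans optional list of [parcel_ts()] (otherwise `config$simulate`
#'   must be set).
#' @param systems optional [system_partition()] for template analyses.
#' @return List with `patterns`, `concordance`, `hierarchy`, `fc` (mean
#'   static FC across scans), `depths`, `composition`, `centroids` (kept
#'   level-2 communities), `templates` (when `systems` given), `funnel`,
#'   `truth` (when simulated), and `config`.
#' @export
run_pipeline <- function(config, scans = NULL, systems = NULL) {
  stopifnot(inherits(config, "run_config"))
  truth <- NULL
  if (is.null(scans)) {
    if (is.null(config$simulate))
      stop("no input scans and no `simulate` block in config")
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% derive_seed(config$seed, 1L)
    gen <- generate_state_switching_data(do.call(synthetic_config, sim_args))
    scans <- gen$scans
    truth <- gen$truth
    if (is.null(systems))
      systems <- system_partition(paste0("sys", gen$truth$systems))
  }
  per_scan <- lapply(scans, scan_peak_patterns,
                     pad_frames = config$pad_frames, min_run = config$min_run,
                     min_relative_rms = config$min_relative_rms,
                     min_separation_s = config$min_separation_s,
                     rms_mode = config$rms_mode)
  patterns <- pool_patterns(per_scan)
  funnel <- data.frame(
    scan_id = vapply(scans, function(s) s$scan_id, character(1)),
    frames = vapply(scans, function(s) nrow(s$data), integer(1)),
    usable = vapply(scans, function(s) sum(s$censor), integer(1)),
    segments = vapply(per_scan, function(p) unname(p$funnel["segments"]),
                      numeric(1)),
    peaks = vapply(per_scan, function(p) unname(p$funnel["peaks"]),
                   numeric(1)))
  if (nrow(patterns$edges) < config$min_size)
    stop("pipeline aborted at clustering: only ", nrow(patterns$edges),
         " peak patterns")
  null_rms <- surrogate_peak_rms(scans, config$n_surrogates,
                                 seed = derive_seed(config$seed, 2L),
                                 pad_frames = config$pad_frames,
                                 min_run = config$min_run,
                                 min_relative_rms = config$min_relative_rms,
                                 min_separation_s = config$min_separation_s,
                                 rms_mode = config$rms_mode)
  patterns <- classify_peak_amplitude(patterns, null_rms,
                                      config$hi_pct, config$lo_pct)
  C <- concordance_matrix(patterns)
  H <- recursive_cluster(C, patterns$meta$scan_id, alpha = config$alpha,
                         min_size = config$min_size,
                         min_scans = config$min_scans,
                         n_runs = config$n_runs, n_perm = config$n_perm,
                         seed = derive_seed(config$seed, 3L))
  fcs <- lapply(scans, function(s) static_fc(zscore_parcels(
    s, segment_usable_runs(s, config$pad_frames, config$min_run))))
  fc <- Reduce(`+`, fcs) / length(fcs)
  depths <- hierarchical_depth(H)
  kept2 <- H$communities[H$communities$kept & H$communities$level == 2L, ]
  centroids <- lapply(kept2$id, function(id)
    cluster_centroid(patterns, H$members[[as.character(id)]]))
  names(centroids) <- kept2$id
  templates <- NULL
  if (!is.null(systems) && length(systems$systems) <= 20L) {
    tset <- enumerate_system_templates(systems)
    bips <- t(vapply(seq_len(nrow(patterns$edges)), function(p) {
      m <- edge_to_matrix(patterns$edges[p, ], patterns$n_parcels)
      ev <- leading_eigenmode(m)$vector
      as.integer(frame_bipartition(ev))
    }, integer(patterns$n_parcels)))
    templates <- match_to_templates(bips, tset)
    templates$set <- tset
  }
  out <- list(patterns = patterns, concordance = C, hierarchy = H, fc = fc,
              depths = depths,
              composition = cluster_composition(H, patterns),
              centroids = centroids, templates = templates,
              funnel = funnel, truth = truth, config = config)
  if (!is.null(config$out_dir)) save_pipeline_outputs(out, config$out_dir)
  invisible(out)
}

# serialize the main artifacts as plain text (JSON + TSV)
save_pipeline_outputs <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  H <- out$hierarchy
  jsonlite::write_json(
    list(config = unclass(out$config),
         n_levels = H$n_levels,
         levels = H$levels,
         communities = H$communities,
         funnel = out$funnel),
    file.path(dir, "hierarchy.json"), auto_unbox = TRUE, digits = NA,
    null = "null", dataframe = "rows")
  lab <- do.call(cbind, H$levels)
  colnames(lab) <- paste0("level", seq_len(ncol(lab)))
  write.table(cbind(out$patterns$meta[, c("scan_id", "frame", "rms",
                                          "relative_rms",
                                          "amplitude_class")], lab),
              file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' Command-line entry point
#'
#' `cofluct_cli(c("run-all", "--config", "cfg.json", "--out", "dir"))`
#' runs the full pipeline from a JSON configuration (which must contain a
#' `simulate` block or be accompanied by `--manifest`).  Subcommand
#' `simulate` writes synthetic scans and a manifest to `--out`.
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return Invisibly, the pipeline bundle or output path.
#' @export
cofluct_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1L)
    stop("usage: cofluct <run-all|simulate> [--config f] [--manifest f] ",
         "[--out dir] [--seed n]")
  cmd <- args[1L]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 1L && i < length(args)) args[i + 1L] else default
  }
  config <- if (!is.null(opt("--config"))) read_run_config(opt("--config"))
            else run_config(simulate = list())
  if (!is.null(opt("--seed"))) config$seed <- as.integer(opt("--seed"))
  if (!is.null(opt("--out"))) config$out_dir <- opt("--out")
  if (cmd == "run-all") {
    scans <- NULL; systems <- NULL
    if (!is.null(opt("--manifest"))) {
      man <- load_manifest(opt("--manifest"))
      scans <- man$scans; systems <- man$systems
    }
    invisible(run_pipeline(config, scans, systems))
  } else if (cmd == "simulate") {
    dir <- config$out_dir %||% "."
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    sim_args <- config$simulate %||% list()
    sim_args$seed <- sim_args$seed %||% config$seed
    gen <- generate_state_switching_data(do.call(synthetic_config, sim_args))
    paths <- vapply(gen$scans, function(ts) {
      p <- file.path(dir, paste0(ts$scan_id, ".tsv"))
      write.table(ts$data, p, sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
      cp <- file.path(dir, paste0(ts$scan_id, ".censor"))
      writeLines(as.character(ts$censor), cp)
      p
    }, character(1))
    jsonlite::write_json(
      list(scans = lapply(gen$scans, function(ts)
        list(path = paste0(ts$scan_id, ".tsv"),
             censor = paste0(ts$scan_id, ".censor"),
             tr = ts$tr, scan_id = ts$scan_id))),
      file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(gen$truth[c("events", "super", "systems")],
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    invisible(dir)
  } else stop("unknown subcommand: ", cmd)
}
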