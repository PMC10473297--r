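#' Parcel time-series container
#'
#' Bundles a frames x parcels signal matrix with its repetition time, a
#' per-frame censor mask (1 = usable, low-motion frame) and parcel labels.
#' This is the unit of input for all downstream edge time-series analysis;
#' multi-scan datasets are simply lists of these objects sharing a parcel
#' ordering.
#'
#' @param data numeric matrix, frames (rows) x parcels (columns).
#' @param tr repetition time in seconds per frame.
#' @param censor binary vector of length `nrow(data)`; 1 marks a usable
#'   frame.  Defaults to all-usable.
#' @param scan_id identifier for the scan session.
#' @param parcel_ids parcel labels; defaults to column names or `p1..pN`.
#' @return An object of class `parcel_ts`.
#' @export
parcel_ts <- function(data, tr, censor = NULL, scan_id = "scan1",
                      parcel_ids = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("`data` must be numeric")
  T <- nrow(data); N <- ncol(data)
  if (T < 1L || N < 2L) stop("need at least 1 frame and 2 parcels")
  if (is.null(censor)) censor <- rep(1L, T)
  censor <- as.integer(censor)
  if (length(censor) != T) stop("censor length ", length(censor),
                                " does not match frame count ", T)
  if (!all(censor %in% c(0L, 1L))) stop("censor mask must be binary")
  if (is.null(parcel_ids)) parcel_ids <- colnames(data) %||% paste0("p", seq_len(N))
  usable <- censor == 1L
  if (any(!is.finite(data[usable, , drop = FALSE])))
    stop("non-finite values among usable frames")
  structure(list(data = data, tr = as.numeric(tr), censor = censor,
                 scan_id = as.character(scan_id),
                 parcel_ids = as.character(parcel_ids)),
            class = "parcel_ts")
}

#' @export
print.parcel_ts <- function(x, ...) {
  cat(sprintf("parcel_ts '%s': %d frames x %d parcels, TR %.3g s, %d usable frames\n",
              x$scan_id, nrow(x$data), ncol(x$data), x$tr, sum(x$censor)))
  invisible(x)
}

#' Read a parcel time-series matrix from delimited text
#'
#' @param path path to a TSV/CSV numeric matrix (no header by default).
#' @param layout `"frames_by_parcels"` (rows are frames) or
#'   `"parcels_by_frames"` (rows are parcels; the matrix is transposed).
#' @param tr repetition time in seconds.
#' @param sep field separator, default whitespace/tab.
#' @param header logical; does the file carry a header row of parcel names.
#' @param scan_id scan identifier, defaults to the file name.
#' @return A [parcel_ts()] object (censor mask all-usable).
#' @export
load_parcel_timeseries <- function(path,
                                   layout = c("frames_by_parcels",
                                              "parcels_by_frames"),
                                   tr = 1, sep = "", header = FALSE,
                                   scan_id = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(read.table(path, sep = sep, header = header,
                            colClasses = "numeric"),
                 error = function(e) stop("format error reading ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0L) stop("format error: empty file ", path)
  m <- as.matrix(df)
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("format error: non-finite value at row %d, column %d of %s",
                 bad[1, 1], bad[1, 2], path))
  if (layout == "parcels_by_frames") m <- t(m)
  dimnames(m) <- NULL
  parcel_ids <- if (header && layout == "frames_by_parcels") colnames(df) else NULL
  parcel_ts(m, tr = tr, scan_id = scan_id %||% basename(path),
            parcel_ids = parcel_ids)
}

#' Read a per-frame censor mask
#'
#' One 0/1 value per line; 1 marks a usable (low-motion) frame.
#'
#' @param path file path.
#' @return Integer vector of 0/1.
#' @export
load_censor_mask <- function(path) {
  v <- scan(path, what = numeric(), quiet = TRUE)
  if (!all(v %in% c(0, 1))) stop("censor mask must contain only 0/1")
  as.integer(v)
}

#' Segment usable frames into contiguous runs
#'
#' Frames within `pad_frames` of any censored frame are additionally removed,
#' and remaining contiguous stretches shorter than `min_run` frames are
#' discarded.  Segmentation and peak detection are then carried out per run,
#' never across a censoring gap.
#'
#' @param ts a [parcel_ts()] object.
#' @param pad_frames frames removed on each side of a censored frame
#'   (default 2, i.e. within two TRs of a high-motion frame).
#' @param min_run minimum surviving run length in frames (default 5).
#' @return data.frame with columns `scan_id`, `start`, `end` (0-based,
#'   half-open `[start, end)`), ordered; possibly zero rows.
#' @export
segment_usable_runs <- function(ts, pad_frames = 2L, min_run = 5L) {
  stopifnot(inherits(ts, "parcel_ts"))
  T <- length(ts$censor)
  keep <- ts$censor == 1L
  bad <- which(!keep)
  if (length(bad) > 0L && pad_frames > 0L) {
    for (d in seq_len(pad_frames)) {
      keep[pmax(bad - d, 1L)] <- keep[pmax(bad - d, 1L)] & FALSE
      keep[pmin(bad + d, T)] <- keep[pmin(bad + d, T)] & FALSE
    }
    keep[bad] <- FALSE
  }
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values & r$lengths >= min_run
  out <- data.frame(scan_id = rep(ts$scan_id, sum(ok)),
                    start = starts[ok] - 1L, end = ends[ok],
                    stringsAsFactors = FALSE)
  out[order(out$start), , drop = FALSE]
}

#' System partition of parcels
#'
#' @param labels character vector mapping each parcel to a system, in parcel
#'   order.
#' @param systems optional ordered list of distinct system names; defaults to
#'   order of first appearance.
#' @return Object of class `system_partition` with `labels` and `systems`.
#' @export
system_partition <- function(labels, systems = NULL) {
  labels <- as.character(labels)
  if (anyNA(labels)) stop("every parcel must be mapped to a system")
  if (is.null(systems)) systems <- unique(labels)
  if (!all(labels %in% systems)) stop("labels outside declared system set")
  if (length(systems) < 2L) stop("need at least 2 systems")
  structure(list(labels = labels, systems = systems),
            class = "system_partition")
}

#' Read a parcel-to-system label file
#'
#' Two whitespace/tab-delimited columns: parcel id, system name.  Every
#' parcel in `parcel_ids` must appear exactly once.
#'
#' @param path file path.
#' @param parcel_ids parcel identifiers, in the order used by the time series.
#' @return A [system_partition()] object.
#' @export
load_system_labels <- function(path, parcel_ids) {
  df <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("parcel", "system"))
  idx <- match(as.character(parcel_ids), as.character(df$parcel))
  if (anyNA(idx))
    stop("label error: no system label for parcel(s) ",
         paste(head(parcel_ids[is.na(idx)], 5), collapse = ", "))
  system_partition(df$system[idx])
}

#' Read a multi-scan dataset manifest
#'
#' JSON of the form
#' `{"scans": [{"path": ..., "tr": ..., "scan_id": ..., "censor": ...}, ...],
#'   "systems": <path>, "layout": <layout>}`.
#' Paths are resolved relative to the manifest location.
#'
#' @param path manifest path.
#' @return List with `scans` (list of [parcel_ts()]) and `systems`
#'   (a [system_partition()] or `NULL`).
#' @export
load_manifest <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = FALSE)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (startsWith(p, "/")) p else file.path(base, p)
  layout <- man$layout %||% "frames_by_parcels"
  scans <- lapply(man$scans, function(s) {
    ts <- load_parcel_timeseries(resolve(s$path), layout = layout,
                                 tr = s$tr %||% 1,
                                 scan_id = s$scan_id %||% basename(s$path))
    if (!is.null(s$censor))
      ts <- parcel_ts(ts$data, ts$tr, load_censor_mask(resolve(s$censor)),
                      ts$scan_id, ts$parcel_ids)
    ts
  })
  systems <- NULL
  if (!is.null(man$systems))
    systems <- load_system_labels(resolve(man$systems), scans[[1]]$parcel_ids)
  list(scans = scans, systems = systems)
}
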