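#' Construct an MS1 run from a centroid table
#'
#' An MS1 run is stored as a long tibble of centroids with one row per
#' (scan retention time, m/z, intensity) triple. Scans are identified by
#' their retention time; retention times must be sorted and intensities
#' non-negative. Scans with no centroids are permitted (they simply have no
#' rows) but the set of scan times can be carried explicitly via
#' `scan_times` so empty scans still contribute zero-intensity XIC points.
#'
#' @param centroids Tibble/data frame with columns `rt` (minutes), `mz`
#'   (Th) and `intensity` (>= 0).
#' @param scan_times Optional numeric vector of all scan retention times
#'   (strictly increasing); defaults to the distinct `rt` values present.
#' @return A tibble of class `ms1_run` with attribute `scan_times`.
#' @export
ms1_run <- function(centroids, scan_times = NULL) {
  centroids <- as_tibble(centroids)
  stopifnot(all(c("rt", "mz", "intensity") %in% names(centroids)))
  if (any(centroids$intensity < 0)) abort("Centroid intensities must be >= 0.")
  scan_times <- scan_times %||% sort(unique(centroids$rt))
  if (is.unsorted(scan_times, strictly = TRUE)) {
    abort("Scan retention times must be strictly increasing.")
  }
  if (!all(centroids$rt %in% scan_times)) {
    abort("Every centroid must belong to a listed scan time.")
  }
  out <- arrange(centroids[, c("rt", "mz", "intensity")], .data$rt, .data$mz)
  structure(out, scan_times = as.numeric(scan_times),
            class = c("ms1_run", class(out)))
}

#' @export
#' @rdname ms1_run
#' @param x An object to query.
scan_times <- function(x) attr(x, "scan_times")

#' Read an MS1 run from a scan table TSV
#'
#' Expects tab-separated columns `rt`, `mz`, `intensity` (one row per
#' centroid). Rows with `mz` of `NA` mark empty scans: they contribute their
#' retention time to the scan grid but no centroid.
#'
#' @param path Path to the TSV file.
#' @return An [ms1_run()].
#' @export
read_ms1_tsv <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           rt = readr::col_double(),
                           mz = readr::col_double(),
                           intensity = readr::col_double()
                         ))
  times <- sort(unique(tbl$rt))
  ms1_run(tbl[!is.na(tbl$mz), ], scan_times = times)
}

#' Write an MS1 run to a scan table TSV
#'
#' @param run An [ms1_run()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ms1_tsv <- function(run, path) {
  tbl <- as_tibble(run)
  empty <- setdiff(scan_times(run), unique(tbl$rt))
  if (length(empty) > 0) {
    tbl <- bind_rows(tbl, tibble(rt = empty, mz = NA_real_, intensity = NA_real_))
    tbl <- arrange(tbl, .data$rt, .data$mz)
  }
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' Extract an ion chromatogram at ppm tolerance
#'
#' For every scan whose retention time falls in `rt_window`, sums the
#' intensities of centroids whose m/z lies within `tolerance_ppm` parts per
#' million of `target_mz` (|mz - target| / target * 1e6 <= tolerance).
#' Scans with no matching centroid contribute an intensity of zero, so the
#' trace always has one point per scan in the window.
#'
#' @param run An [ms1_run()].
#' @param target_mz Target m/z (Th).
#' @param tolerance_ppm Mass tolerance in ppm (default 10, the usual
#'   high-resolution MS1 setting).
#' @param rt_window Length-2 numeric `(start, end)` in minutes, or `NULL`
#'   for the whole run.
#' @return A tibble of class `xic_trace` with columns `rt`, `intensity` and
#'   attributes `target_mz`, `tolerance_ppm`.
#' @export
extract_xic <- function(run, target_mz, tolerance_ppm = 10, rt_window = NULL) {
  stopifnot(inherits(run, "ms1_run"))
  if (tolerance_ppm <= 0) abort("`tolerance_ppm` must be > 0.")
  times <- scan_times(run)
  if (length(times) == 0) {
    return(new_xic(tibble(rt = numeric(), intensity = numeric()),
                   target_mz, tolerance_ppm))
  }
  if (is.null(rt_window)) rt_window <- range(times)
  if (rt_window[1] > rt_window[2]) {
    abort("`rt_window` is inverted: start must be <= end.")
  }
  in_win <- times >= rt_window[1] & times <= rt_window[2]
  win_times <- times[in_win]
  tol <- target_mz * tolerance_ppm * 1e-6
  hits <- filter(
    as_tibble(run),
    .data$rt >= rt_window[1], .data$rt <= rt_window[2],
    abs(.data$mz - target_mz) <= tol
  )
  summed <- summarise(group_by(hits, .data$rt),
                      intensity = sum(.data$intensity), .groups = "drop")
  trace <- left_join(tibble(rt = win_times), summed, by = "rt")
  trace$intensity[is.na(trace$intensity)] <- 0
  new_xic(trace, target_mz, tolerance_ppm)
}

new_xic <- function(points, target_mz, tolerance_ppm) {
  structure(points, target_mz = target_mz, tolerance_ppm = tolerance_ppm,
            class = c("xic_trace", class(points)))
}

#' Integrate an XIC peak area
#'
#' Baseline-subtracted trapezoidal integration: the baseline is the minimum
#' intensity in the trace window, baseline-subtracted intensities are
#' clipped below at zero, and the area is the trapezoidal integral over
#' retention time (intensity x minutes). A transparent, reproducible stand-in
#' for vendor chromatographic-area algorithms; shape-agnostic, so it makes
#' no assumption about peak symmetry.
#'
#' @param trace An `xic_trace` (or any tibble with `rt` and `intensity`).
#' @return Integrated area (intensity x minutes); 0 for an all-zero or
#'   single-point trace.
#' @export
integrate_area <- function(trace) {
  if (nrow(trace) < 1) abort("Trace must contain at least one point.")
  if (nrow(trace) == 1) return(0)
  y <- pmax(trace$intensity - min(trace$intensity), 0)
  x <- trace$rt
  sum((y[-1] + y[-length(y)]) / 2 * diff(x))
}
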