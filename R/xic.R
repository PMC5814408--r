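# XIC extraction and chromatographic peak detection.
#
# An MS1 map is a plain tibble of centroids with columns `scan` (integer id),
# `rt` (minutes), `mz` (Th) and `intensity`, sorted by retention time.
# The exported functions are tidy wrappers around base-vector internals kept
# lean because they sit in the per-peptide hot loop.

.check_ms1_map <- function(ms1) {
  need <- c("scan", "rt", "mz", "intensity")
  if (!all(need %in% names(ms1))) {
    abort(paste0("MS1 map needs columns: ", paste(need, collapse = ", ")))
  }
  ord <- order(ms1$scan)
  rt_by_scan <- ms1$rt[ord][!duplicated(ms1$scan[ord])]
  if (is.unsorted(rt_by_scan)) abort("MS1 spectra must be sorted by retention time.")
  invisible(ms1)
}

# Trace matrix (scans x targets) of summed centroid intensities within
# tolerance, over the scans inside the RT window. Returns NULL if no scans.
.xic_matrix <- function(ms1, mz_targets, rt_center, window, tol_ppm) {
  half <- window / 2
  inside <- ms1$rt >= rt_center - half & ms1$rt <= rt_center + half
  scan <- ms1$scan[inside]
  if (length(scan) == 0) return(NULL)
  mz <- ms1$mz[inside]
  intensity <- ms1$intensity[inside]
  scan_ids <- sort(unique(scan))
  rt_of <- ms1$rt[inside][match(scan_ids, scan)]
  scan_idx <- match(scan, scan_ids)
  mat <- matrix(0, nrow = length(scan_ids), ncol = length(mz_targets))
  for (k in seq_along(mz_targets)) {
    tol <- mz_targets[k] * tol_ppm * 1e-6
    hit <- which(abs(mz - mz_targets[k]) <= tol)
    if (length(hit) > 0) {
      sums <- rowsum(intensity[hit], scan_idx[hit])
      mat[as.integer(rownames(sums)), k] <- sums[, 1]
    }
  }
  list(scan = scan_ids, rt = rt_of, mat = mat)
}

#' Extract ion chromatograms around a retention time
#'
#' For every target m/z, sums the intensities of all centroids within
#' `tol_ppm` of the target, per scan, over a retention-time window centred on
#' `rt_center`. Scans inside the window with no matching centroid contribute
#' zero, so all traces share the same scan grid.
#'
#' @param ms1 MS1 map tibble (`scan`, `rt`, `mz`, `intensity`), RT-sorted.
#' @param mz_targets Numeric vector of target m/z values (Th).
#' @param rt_center Window centre (minutes).
#' @param window Window width in minutes (the trace covers
#'   `rt_center +/- window / 2`).
#' @param tol_ppm Matching tolerance in parts per million.
#' @return Tibble with columns `target` (index into `mz_targets`),
#'   `target_mz`, `scan`, `rt`, `intensity`.
#' @export
extract_xics <- function(ms1, mz_targets, rt_center, window = 1, tol_ppm = 7) {
  stopifnot(window > 0, length(mz_targets) >= 1)
  .check_ms1_map(ms1)
  tr <- .xic_matrix(ms1, mz_targets, rt_center, window, tol_ppm)
  if (is.null(tr)) {
    return(tibble(target = integer(), target_mz = numeric(), scan = integer(),
                  rt = numeric(), intensity = numeric()))
  }
  n_scan <- length(tr$scan)
  tibble(
    target = rep(seq_along(mz_targets), each = n_scan),
    target_mz = rep(mz_targets, each = n_scan),
    scan = rep(tr$scan, times = length(mz_targets)),
    rt = rep(tr$rt, times = length(mz_targets)),
    intensity = as.numeric(tr$mat)
  )
}

# Base peak detector: returns a data.frame (possibly 0 rows) with apex_rt,
# apex_intensity, left50, right50.
.detect_peaks_base <- function(rt, raw, min_intensity = 0) {
  none <- data.frame(apex_rt = numeric(), apex_intensity = numeric(),
                     left50 = numeric(), right50 = numeric())
  n <- length(raw)
  if (n < 3 || all(raw <= 0)) return(none)
  sm <- c(raw[1],
          (raw[1:(n - 2)] + raw[2:(n - 1)] + raw[3:n]) / 3,
          raw[n])
  floor_i <- max(min_intensity, 3 * median(raw))
  cand <- which(sm[2:(n - 1)] >= sm[1:(n - 2)] & sm[2:(n - 1)] > sm[3:n]) + 1L
  cand <- cand[raw[cand] > floor_i & raw[cand] > 0]
  if (length(cand) == 0) return(none)
  out <- lapply(cand, function(i) {
    nb <- max(1L, i - 1L):min(n, i + 1L)
    i <- nb[which.max(raw[nb])]
    apex <- raw[i]
    half <- apex / 2
    left <- rt[1]
    if (i > 1L) {
      for (j in seq(i - 1L, 1L, by = -1L)) {
        if (raw[j] <= half) {
          left <- rt[j] + (rt[j + 1] - rt[j]) * (half - raw[j]) / (raw[j + 1] - raw[j])
          break
        }
      }
    }
    right <- rt[n]
    if (i < n) {
      for (j in seq(i + 1L, n, by = 1L)) {
        if (raw[j] <= half) {
          right <- rt[j - 1] + (rt[j] - rt[j - 1]) * (raw[j - 1] - half) / (raw[j - 1] - raw[j])
          break
        }
      }
    }
    c(rt[i], apex, left, right)
  })
  out <- do.call(rbind, out)
  out <- out[!duplicated(out[, 1]), , drop = FALSE]
  data.frame(apex_rt = out[, 1], apex_intensity = out[, 2],
             left50 = out[, 3], right50 = out[, 4])
}

#' Detect chromatographic peaks in an XIC trace
#'
#' Applies 3-point moving-average smoothing, takes local maxima of the
#' smoothed trace whose raw intensity exceeds
#' `max(min_intensity, 3 * median(raw))`, and locates the two 50%-apex
#' boundary times by linear interpolation on the raw trace (window edges are
#' used when the trace never drops below half height).
#'
#' @param xic Tibble with columns `rt` and `intensity`, ordered by `rt`.
#' @param min_intensity Absolute noise floor for apexes.
#' @return Tibble with one row per peak: `apex_rt`, `apex_intensity`,
#'   `left50`, `right50` (all times in minutes). Empty on flat or too-short
#'   traces.
#' @export
detect_peaks <- function(xic, min_intensity = 0) {
  ord <- order(xic$rt)
  as_tibble(.detect_peaks_base(xic$rt[ord], xic$intensity[ord], min_intensity))
}
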