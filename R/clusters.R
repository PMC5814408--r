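# Isotope-cluster assembly and least-squares envelope fitting.

# Base implementation over a data.frame of peaks with an `isotope` column;
# returns a list of data.frames, one per surviving candidate.
.build_clusters_base <- function(peaks) {
  if (nrow(peaks) == 0) return(list())
  mono <- peaks[peaks$isotope == 0L, , drop = FALSE]
  if (nrow(mono) == 0) return(list())
  higher <- peaks[peaks$isotope > 0L, , drop = FALSE]
  out <- vector("list", nrow(mono))
  for (i in seq_len(nrow(mono))) {
    m0 <- mono[i, ]
    rows <- list(m0)
    for (iso in sort(unique(higher$isotope))) {
      p <- higher[higher$isotope == iso, , drop = FALSE]
      overlap <- pmin(p$right50, m0$right50) - pmax(p$left50, m0$left50)
      ok <- which(overlap >= 0)
      if (length(ok) == 0) next
      # largest 50%-interval overlap wins; ties by apex proximity
      best <- ok[order(-overlap[ok], abs(p$apex_rt[ok] - m0$apex_rt))][1]
      rows[[length(rows) + 1L]] <- p[best, , drop = FALSE]
    }
    out[[i]] <- do.call(rbind, rows)
  }
  Filter(function(cl) 1L %in% cl$isotope, out)
}

#' Assemble isotope-cluster candidates from per-isotope peak lists
#'
#' Each peak detected in the monoisotopic (isotope 0) XIC anchors one
#' candidate cluster. For every higher isotope index, the peak whose
#' 50%-apex interval overlaps the monoisotopic peak's interval is attached
#' (at most one per index; the largest-overlap peak wins, ties resolved by
#' apex proximity). Candidates whose first 13C isotope (index 1) is missing
#' are removed.
#'
#' @param peaks Tibble of detected peaks with columns `isotope`, `apex_rt`,
#'   `apex_intensity`, `left50`, `right50`.
#' @return List of candidate clusters, each a tibble with the same columns,
#'   one row per isotope index present.
#' @export
build_clusters <- function(peaks) {
  lapply(.build_clusters_base(as.data.frame(peaks)),
         function(cl) as_tibble(cl[order(cl$isotope), ]))
}

#' Least-squares fit of a theoretical envelope to observed intensities
#'
#' The fitted intensity is the least-squares scale factor of the theoretical
#' relative intensities against the observed apex intensities (over isotope
#' positions that were observed). The fit quality is the residual sum of
#' squares after both vectors are normalised to sum 1, with missing isotopes
#' counted as zero; it is therefore scale-invariant, while the fitted
#' intensity is linear in the signal.
#'
#' @param observed Numeric vector of observed intensities, one entry per
#'   envelope isotope index (ordered as in `envelope`); `NA` marks a missing
#'   isotope.
#' @param envelope An `isotope_envelope` covering the observed indices.
#' @return List with `fitted_intensity` and `fit_quality` (both `NA` when the
#'   observations are all missing or all zero, or fewer than two isotopes
#'   were observed).
#' @export
fit_cluster <- function(observed, envelope) {
  theo <- envelope$intensity
  stopifnot(length(observed) == length(theo))
  present <- !is.na(observed)
  if (sum(present) < 2 || sum(observed[present]) <= 0) {
    return(list(fitted_intensity = NA_real_, fit_quality = NA_real_))
  }
  scale <- sum(theo[present] * observed[present]) / sum(theo[present]^2)
  obs0 <- ifelse(present, observed, 0)
  o <- obs0 / sum(obs0)
  th <- theo / sum(theo)
  list(fitted_intensity = scale, fit_quality = sum((o - th)^2))
}

# Summed centroid intensity at one m/z position among (mz, intensity) vectors.
.intensity_at <- function(mz, intensity, target, tol_ppm) {
  tol <- target * tol_ppm * 1e-6
  sum(intensity[abs(mz - target) <= tol])
}
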