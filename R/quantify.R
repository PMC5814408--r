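# SILAC pair quantification of one PCM (peptide / charge / modification
# group) from an MS1 map. The internals work on base vectors: this is the
# pipeline's hot loop.

# Fit every cluster candidate, pick the best by fit quality (ties: highest
# fitted intensity, then earliest apex).
.best_xic_fit <- function(clusters, envelope) {
  if (length(clusters) == 0) return(NULL)
  fits <- lapply(clusters, function(cl) {
    observed <- rep(NA_real_, nrow(envelope))
    keep <- cl$isotope < nrow(envelope)
    observed[cl$isotope[keep] + 1L] <- cl$apex_intensity[keep]
    f <- fit_cluster(observed, envelope)
    f$apex_rt <- cl$apex_rt[cl$isotope == 0L][1]
    f
  })
  fits <- Filter(function(f) is.finite(f$fit_quality), fits)
  if (length(fits) == 0) return(NULL)
  ord <- order(vapply(fits, `[[`, numeric(1), "fit_quality"),
               -vapply(fits, `[[`, numeric(1), "fitted_intensity"),
               vapply(fits, `[[`, numeric(1), "apex_rt"))
  fits[[ord[1]]]
}

# Quantify one label state of one PCM. `sub` holds the centroids of the RT
# window as plain vectors. Returns fitted intensity, fit quality, the
# cluster source used (XIC / AS / PS) and the prior-ion ratio.
.quantify_label <- function(sub, envelope, pcm_rt, config) {
  undetermined <- list(intensity = NA_real_, fit_quality = NA_real_,
                       prior_ratio = NA_real_, source = NA_character_)
  tr <- .xic_matrix(sub, envelope$mz, pcm_rt, config$xic_window, config$tol_ppm)
  if (is.null(tr)) return(undetermined)

  peak_list <- lapply(seq_len(ncol(tr$mat)), function(k) {
    p <- .detect_peaks_base(tr$rt, tr$mat[, k], config$peak_min_intensity)
    if (nrow(p) > 0) p$isotope <- k - 1L
    p
  })
  peaks <- do.call(rbind, Filter(function(p) nrow(p) > 0, peak_list))
  best <- if (!is.null(peaks)) {
    .best_xic_fit(.build_clusters_base(peaks), envelope)
  } else NULL

  results <- list()
  if (!is.null(best)) results$XIC <- best
  # fall back to single-spectrum clusters when the chromatographic fit is poor
  if (is.null(best) || best$fit_quality > config$max_fit) {
    apex_rt <- if (!is.null(best)) best$apex_rt else pcm_rt
    as_scan <- tr$scan[which.min(abs(tr$rt - apex_rt))]
    before <- which(tr$rt < pcm_rt)
    ps_scan <- if (length(before) > 0) tr$scan[max(before)] else NA_integer_
    for (src in c("AS", "PS")) {
      scan_id <- if (src == "AS") as_scan else ps_scan
      if (is.na(scan_id)) next
      in_scan <- sub$scan == scan_id
      obs <- vapply(envelope$mz, function(m) {
        .intensity_at(sub$mz[in_scan], sub$intensity[in_scan], m, config$tol_ppm)
      }, numeric(1))
      obs[obs <= 0] <- NA_real_
      f <- fit_cluster(obs, envelope)
      if (is.finite(f$fit_quality)) {
        f$apex_rt <- tr$rt[tr$scan == scan_id][1]
        results[[src]] <- f
      }
    }
  }
  if (length(results) == 0) return(undetermined)
  src <- names(results)[which.min(vapply(results, `[[`, numeric(1), "fit_quality"))]
  sel <- results[[src]]
  fitted_sum <- sel$fitted_intensity * sum(envelope$intensity)

  # prior ion: one neutron below the monoisotopic peak, measured in the
  # survey scan at the apex of the selected cluster
  apex_scan <- tr$scan[which.min(abs(tr$rt - sel$apex_rt))]
  charge <- attr(envelope, "charge")
  prior_mz <- envelope$mz[1] - .neutron_mass / charge
  in_scan <- sub$scan == apex_scan
  prior_int <- .intensity_at(sub$mz[in_scan], sub$intensity[in_scan],
                             prior_mz, config$tol_ppm)
  prior_ratio <- if (fitted_sum > 0) prior_int / fitted_sum else NA_real_

  list(intensity = fitted_sum, fit_quality = sel$fit_quality,
       prior_ratio = prior_ratio, source = src)
}

#' Quantify the SILAC pair of one PCM
#'
#' For each label state the theoretical envelope is fitted to the isotope
#' cluster candidates assembled from the XICs; if the best chromatographic
#' fit exceeds `max_fit`, single-spectrum clusters from the apex survey scan
#' (AS) and the preceding survey scan (PS) are fitted too and the best of the
#' three is kept. The quantification value is the sum of the theoretical
#' intensities times the fitted intensity; the heavy/light ratio is defined
#' when both label intensities are positive.
#'
#' @param pcm A one-row tibble or list with `sequence`, `charge`,
#'   `modifications` (label-agnostic token string, `";"`-separated, may be
#'   empty) and `rt` (minutes).
#' @param ms1 MS1 map tibble.
#' @param config A [run_config()].
#' @return One-row tibble with light/heavy intensities, `ratio_hl`, per-label
#'   fit qualities, prior-ion ratios and the cluster source used.
#' @export
quantify_pcm <- function(pcm, ms1, config = run_config()) {
  mods <- pcm$modifications %||% ""
  mods <- if (is.na(mods) || !nzchar(mods)) character() else strsplit(mods, ";")[[1]]
  half <- config$xic_window / 2
  inside <- ms1$rt >= pcm$rt - half & ms1$rt <= pcm$rt + half
  sub <- list(scan = ms1$scan[inside], rt = ms1$rt[inside],
              mz = ms1$mz[inside], intensity = ms1$intensity[inside])
  out <- lapply(c(light = "light", heavy = "heavy"), function(lab) {
    comp <- composition_of_peptide(pcm$sequence, mods, label = lab)
    env <- exact_envelope(comp, pcm$charge, config$n_isotopes)
    .quantify_label(sub, env, pcm$rt, config)
  })
  li <- out$light$intensity
  hi <- out$heavy$intensity
  ratio <- if (isTRUE(li > 0) && isTRUE(hi > 0)) hi / li else NA_real_
  tibble(
    sequence = pcm$sequence, charge = as.integer(pcm$charge),
    modifications = paste(mods, collapse = ";"), rt = pcm$rt,
    light_intensity = li, heavy_intensity = hi, ratio_hl = ratio,
    fit_light = out$light$fit_quality, fit_heavy = out$heavy$fit_quality,
    prior_light = out$light$prior_ratio, prior_heavy = out$heavy$prior_ratio,
    source_light = out$light$source, source_heavy = out$heavy$source
  )
}

#' Quantify every PCM of a run
#'
#' @param pcms Tibble of PCM records (see [quantify_pcm()] for the required
#'   columns; extra columns are carried through).
#' @param ms1 MS1 map tibble.
#' @param config A [run_config()].
#' @return Tibble with one row per PCM: the input columns joined with the
#'   quantification results.
#' @export
quantify_pcms <- function(pcms, ms1, config = run_config()) {
  .check_ms1_map(ms1)
  quant <- purrr::map_dfr(seq_len(nrow(pcms)), function(i) {
    quantify_pcm(as.list(pcms[i, ]), ms1, config) |>
      select(-"sequence", -"charge", -"modifications", -"rt")
  })
  bind_cols(pcms, quant)
}
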