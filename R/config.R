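#' Pipeline configuration
#'
#' Collects every tunable threshold of the workflow with its default. The
#' quantification filters mirror the protein-quantification filter cascade
#' (score > 15, length >= 6, peptide FDR <= 1%, envelope fit of both label
#' states <= 0.1, prior-ion ratio of both label states <= 0.2); the XIC
#' settings and quality cutoffs are documented per argument.
#'
#' @param tol_ppm XIC and survey-scan m/z matching tolerance (ppm).
#' @param xic_window XIC retention-time window width (minutes).
#' @param peak_min_intensity Absolute noise floor for peak detection.
#' @param n_isotopes Envelope length; `NULL` for the automatic 0.999
#'   cumulative-probability rule (capped at 8).
#' @param min_score Minimum search-engine score (exclusive) for quantification.
#' @param min_length Minimum peptide length (inclusive).
#' @param max_fdr Peptide-level FDR threshold.
#' @param max_fit Maximum envelope fit residual for both label states.
#' @param max_prior_ratio Maximum prior-ion ratio for both label states.
#' @param r2_high R-squared cutoff defining the high-quality half-life subset.
#' @param r2_colormap R-squared cutoff for structure colour maps.
#' @param time_points Sampling times of the pulse design (hours).
#' @param n_shuffles Shuffle count for the complex-coherence test.
#' @param decoy_prefix Accession prefix marking decoy proteins.
#' @param seed Integer seed used by the pipeline's stochastic steps.
#' @return A named list of class `dynsilac_config`.
#' @export
run_config <- function(tol_ppm = 7,
                       xic_window = 1,
                       peak_min_intensity = 0,
                       n_isotopes = NULL,
                       min_score = 15,
                       min_length = 6,
                       max_fdr = 0.01,
                       max_fit = 0.1,
                       max_prior_ratio = 0.2,
                       r2_high = 0.85,
                       r2_colormap = 0.25,
                       time_points = c(7, 11, 24, 34),
                       n_shuffles = 1000,
                       decoy_prefix = "DECOY_",
                       seed = 1L) {
  cfg <- list(
    tol_ppm = tol_ppm, xic_window = xic_window,
    peak_min_intensity = peak_min_intensity, n_isotopes = n_isotopes,
    min_score = min_score, min_length = min_length, max_fdr = max_fdr,
    max_fit = max_fit, max_prior_ratio = max_prior_ratio,
    r2_high = r2_high, r2_colormap = r2_colormap,
    time_points = time_points, n_shuffles = n_shuffles,
    decoy_prefix = decoy_prefix, seed = as.integer(seed)
  )
  structure(cfg, class = c("dynsilac_config", "list"))
}

#' Read / write a configuration file
#'
#' Configurations serialise to plain-text YAML so a run is reproducible from
#' its config file alone.
#'
#' @param path File path.
#' @return `read_config()` returns a `dynsilac_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  defaults <- run_config()
  unknown <- setdiff(names(vals), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("Unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  do.call(run_config, vals)
}

#' @rdname read_config
#' @param config A `dynsilac_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config[!vapply(config, is.null, logical(1))], path)
  invisible(path)
}
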