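# End-to-end pipeline: PSMs + spectra -> half-lives (and complex analyses).

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("Pipeline stage '", name, "' failed: ", conditionMessage(e)))
  })
}

#' Run the full turnover pipeline
#'
#' Stages: condense PSMs to PCMs; peptide target-decoy FDR; protein group
#' inference; per-run SILAC pair quantification; protein fold changes per
#' run through the filter cascade; turnover fits per protein and replicate;
#' replicate-merged half-life summary; optional complex-coherence test. Each
#' stage logs its casualty counts; failures abort with the stage named.
#'
#' @param config A [run_config()].
#' @param psms PSM tibble (see [condense_to_pcms()]).
#' @param spectra Named list of MS1 map tibbles, one per run in `design`.
#' @param design Tibble (`run`, `replicate`, `time_h`).
#' @param complexes Optional complex membership tibble
#'   (`complex_id`, `accession` matching protein group ids).
#' @param gene_map Optional (`accession`, `gene`) table for group merging.
#' @return List of result tables: `pcms`, `groups`, `protein_fdr`,
#'   `peptide_quant`, `fold_changes`, `turnover_fits`, `halflife_summary`,
#'   and `coherence` (a `complex_coherence` object or `NULL`).
#' @export
run_pipeline <- function(config, psms, spectra, design,
                         complexes = NULL, gene_map = NULL) {
  if (nrow(psms) == 0) abort("Pipeline stage 'condense': empty PSM table.")
  missing_runs <- setdiff(design$run, names(spectra))
  if (length(missing_runs) > 0) {
    abort(paste0("Pipeline stage 'input': no spectra for run(s) ",
                 paste(missing_runs, collapse = ", ")))
  }

  pcms <- .stage("condense", peptide_fdr(condense_to_pcms(psms)))
  inform(paste0("condense: ", nrow(pcms), " PCMs from ", nrow(psms), " PSMs (",
                sum(pcms$is_decoy), " decoy)"))

  groups <- .stage("protein inference",
                   infer_protein_groups(pcms, gene_map, max_fdr = config$max_fdr))
  inform(paste0("protein inference: ", nrow(groups), " groups"))

  protein_scores <- .stage("protein FDR", {
    pcms |>
      mutate(accession = strsplit(.data$accessions, ";")) |>
      tidyr::unnest("accession") |>
      group_by(.data$accession) |>
      summarise(score = sum(.data$best_score),
                is_decoy = .data$is_decoy[1], .groups = "drop") |>
      picked_protein_fdr(decoy_prefix = config$decoy_prefix)
  })

  quant_in <- pcms |> filter(!.data$is_decoy, .data$q_value <= config$max_fdr)
  quants <- .stage("quantification", {
    purrr::map_dfr(design$run, function(r) {
      run_pcms <- filter(quant_in, .data$run == r)
      if (nrow(run_pcms) == 0) return(NULL)
      quantify_pcms(run_pcms, spectra[[r]], config)
    })
  })
  inform(paste0("quantification: ", sum(!is.na(quants$ratio_hl)), " of ",
                nrow(quants), " PCM quantifications with a defined H/L ratio"))

  fold_changes <- .stage("fold change", {
    quants |>
      group_by(.data$run) |>
      group_modify(~ protein_fold_changes(.x, groups, config)) |>
      ungroup() |>
      left_join(design, by = "run")
  })
  inform(paste0("fold change: ", sum(!is.na(fold_changes$fold_change)),
                " defined protein fold changes across runs"))

  fits <- .stage("turnover", {
    fold_changes |>
      rename(protein = "group_id", ratio = "fold_change") |>
      fit_turnover(n_design = length(config$time_points))
  })

  summary <- .stage("replicate merge", {
    if (n_distinct(design$replicate) >= 2) {
      merge_replicates(fits, min_r2 = config$r2_high)
    } else {
      tibble(protein = character(), n_replicates = integer(),
             t_half_mean = numeric(), log10_t_half = numeric(),
             t_half_by_replicate = list())
    }
  })
  inform(paste0("replicate merge: ", nrow(summary),
                " proteins with a merged high-quality half-life"))

  coherence <- NULL
  if (!is.null(complexes) && nrow(summary) > 0) {
    coherence <- .stage("complex coherence", {
      hl <- summary |> select(accession = "protein", t_half = "t_half_mean")
      tryCatch(
        complex_coherence_test(hl, complexes, n_shuffles = config$n_shuffles,
                               seed = config$seed),
        error = function(e) {
          warn(paste0("Coherence test skipped: ", conditionMessage(e)))
          NULL
        }
      )
    })
  }

  list(pcms = pcms, groups = groups, protein_fdr = protein_scores,
       peptide_quant = quants, fold_changes = fold_changes,
       turnover_fits = fits, halflife_summary = summary,
       coherence = coherence)
}

#' Write pipeline result tables to a directory
#'
#' Serialises every tabular result as TSV with deterministic formatting, so
#' two runs with identical seed and configuration produce byte-identical
#' files.
#'
#' @param results Output of [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_results <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- c("pcms", "groups", "protein_fdr", "peptide_quant",
              "fold_changes", "turnover_fits", "halflife_summary")
  for (name in tables) {
    tab <- results[[name]]
    if (!is.null(tab) && nrow(tab) > 0) {
      suppressMessages(write_table_tsv(tab, file.path(dir, paste0(name, ".tsv"))))
    }
  }
  if (!is.null(results$coherence)) {
    suppressMessages(write_table_tsv(glance(results$coherence),
                                     file.path(dir, "coherence.tsv")))
  }
  invisible(dir)
}
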