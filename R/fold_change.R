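# Protein fold-change aggregation from filtered peptide ratios.

# The five-filter cascade applied to one peptide quant row. NA fit or prior
# values (label state never measured) do not fail the fit/prior filters: the
# corresponding ratio is simply undetermined.
.passes_quant_filters <- function(quants, filters) {
  ok_fit <- function(x) is.na(x) | x <= filters$max_fit
  ok_prior <- function(x) is.na(x) | x <= filters$max_prior_ratio
  quants$best_score > filters$min_score &
    nchar(quants$sequence) >= filters$min_length &
    quants$q_value <= filters$max_fdr &
    ok_fit(quants$fit_light) & ok_fit(quants$fit_heavy) &
    ok_prior(quants$prior_light) & ok_prior(quants$prior_heavy)
}

#' Protein fold change from unique peptide ratios
#'
#' Applies the quantification filter cascade (score, length, peptide FDR,
#' both-label envelope fit, both-label prior-ion ratio) to the unique
#' peptides of one protein group and returns the median of the surviving
#' heavy/light ratios. When at least one surviving peptide has a positive
#' ratio, peptides with an undetermined ratio are excluded from the median;
#' when none does, the fold change is undetermined (`NA`).
#'
#' @param quants Tibble of peptide quantifications for one protein group,
#'   with columns `sequence`, `best_score`, `q_value`, `ratio_hl`,
#'   `fit_light`, `fit_heavy`, `prior_light`, `prior_heavy`.
#' @param filters A [run_config()] (only the filter fields are used).
#' @return List with `fold_change` (median H/L ratio or `NA`) and
#'   `n_peptides` (surviving peptides with a defined ratio).
#' @export
protein_fold_change <- function(quants, filters = run_config()) {
  surviving <- quants[.passes_quant_filters(quants, filters), ]
  ratios <- surviving$ratio_hl
  defined <- ratios[!is.na(ratios) & ratios > 0]
  if (length(defined) == 0) {
    return(list(fold_change = NA_real_, n_peptides = 0L))
  }
  list(fold_change = median(defined), n_peptides = length(defined))
}

#' Fold changes for all protein groups of a run
#'
#' Joins peptide quantifications to protein groups via unique peptides and
#' aggregates one fold change per group.
#'
#' @param quants Peptide quantification tibble (see [quantify_pcms()]) with
#'   `best_score` and `q_value` columns.
#' @param groups Protein groups from [infer_protein_groups()].
#' @param filters A [run_config()].
#' @return Tibble (`group_id`, `fold_change`, `n_peptides`).
#' @export
protein_fold_changes <- function(quants, groups, filters = run_config()) {
  pmap <- protein_peptide_map(groups) |> filter(.data$unique)
  joined <- quants |>
    inner_join(select(pmap, "group_id", "sequence"), by = "sequence")
  joined |>
    group_by(.data$group_id) |>
    group_modify(function(df, key) {
      res <- protein_fold_change(df, filters)
      tibble(fold_change = res$fold_change, n_peptides = res$n_peptides)
    }) |>
    ungroup()
}
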