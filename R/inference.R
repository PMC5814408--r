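# PSM condensing, target-decoy FDR, protein grouping and picked-protein FDR.

# The quantification label is not part of the PCM identity: strip the SILAC
# token so light and heavy identifications of a peptide condense together.
.strip_label <- function(modifications) {
  vapply(modifications, function(m) {
    if (is.na(m) || !nzchar(m)) return("")
    toks <- strsplit(m, ";")[[1]]
    paste(sort(toks[toks != "Heavy"]), collapse = ";")
  }, character(1), USE.NAMES = FALSE)
}

#' Condense PSMs into PCM records
#'
#' Groups peptide-spectrum matches by run, sequence, charge and the
#' label-agnostic modification string (SILAC label tokens ignored), and keeps
#' the highest-scoring PSM as the representative of each group (ties broken
#' by the earliest scan). The score margin of the representative — its score
#' minus the best score of a different sequence matched to the same spectrum,
#' or the score itself when the spectrum has no competitor — is carried along
#' for protein inference.
#'
#' @param psms Tibble with columns `run`, `scan`, `rt`, `sequence`, `charge`,
#'   `modifications`, `score`, `accessions` (`";"`-separated), `is_decoy`.
#' @return Tibble of PCM records, one row per (run, sequence, charge,
#'   label-agnostic modifications), with `best_score`, `score_margin`,
#'   `n_psms` and the representative's `rt`/`scan`.
#' @export
condense_to_pcms <- function(psms) {
  psms <- psms |>
    group_by(.data$run, .data$scan) |>
    mutate(.rival = {
      best_other <- vapply(seq_along(.data$score), function(i) {
        other <- .data$score[.data$sequence != .data$sequence[i]]
        if (length(other) == 0) 0 else max(other)
      }, numeric(1))
      best_other
    }) |>
    ungroup() |>
    mutate(score_margin = .data$score - .data$.rival,
           mod_key = .strip_label(.data$modifications))
  psms |>
    group_by(.data$run, .data$sequence, .data$charge, .data$mod_key) |>
    arrange(desc(.data$score), .data$scan, .by_group = TRUE) |>
    summarise(
      best_score = first(.data$score),
      score_margin = first(.data$score_margin),
      rt = first(.data$rt),
      scan = first(.data$scan),
      accessions = paste(sort(unique(unlist(strsplit(.data$accessions, ";")))),
                         collapse = ";"),
      is_decoy = first(.data$is_decoy),
      n_psms = n(),
      .groups = "drop"
    ) |>
    rename(modifications = "mod_key")
}

# Classical target-decoy FDR at descending score, monotonised into q-values.
.target_decoy_q <- function(score, is_decoy) {
  ord <- order(score, decreasing = TRUE)
  n_decoy <- cumsum(is_decoy[ord])
  n_target <- cumsum(!is_decoy[ord])
  fdr <- ifelse(n_target > 0, n_decoy / n_target, 1)
  q <- rev(cummin(rev(fdr)))
  out <- numeric(length(score))
  out[ord] <- q
  out
}

#' Peptide-level target-decoy FDR
#'
#' Adds a `q_value` column: the minimum FDR (#decoys / #targets at or above
#' a score threshold) at which the peptide would still be accepted.
#'
#' @param pcms Tibble with `best_score` and `is_decoy` columns.
#' @return The input with a `q_value` column appended.
#' @export
peptide_fdr <- function(pcms) {
  mutate(pcms, q_value = .target_decoy_q(.data$best_score, .data$is_decoy))
}

#' Infer protein groups from FDR-filtered peptides
#'
#' Builds protein groups from peptides passing the FDR threshold: proteins
#' with identical peptide sets share a group; groups whose peptide set is
#' fully contained in a higher-scoring group are aggregated into it; each
#' reported group must contain an anchor peptide of length at least
#' `anchor_length` with a score margin of at least `anchor_margin`; groups
#' sharing a gene identifier are merged. Peptides found in exactly one group
#' are marked unique.
#'
#' @param pcms Tibble of PCM records carrying `q_value` (see
#'   [peptide_fdr()]), `accessions`, `best_score`, `score_margin`.
#' @param gene_map Optional tibble (`accession`, `gene`) used for the
#'   gene-level merge.
#' @param max_fdr Peptide q-value threshold (default 1%).
#' @param anchor_length,anchor_margin Anchor-peptide rules.
#' @return Tibble with one row per protein group: `group_id`, `accessions`,
#'   `genes`, `total_score`, `n_peptides`, and a `peptides` list-column of
#'   tibbles (`sequence`, `best_score`, `unique`).
#' @export
infer_protein_groups <- function(pcms, gene_map = NULL, max_fdr = 0.01,
                                 anchor_length = 7, anchor_margin = 10) {
  pep <- pcms |>
    filter(!.data$is_decoy, .data$q_value <= max_fdr) |>
    group_by(.data$sequence) |>
    summarise(best_score = max(.data$best_score),
              score_margin = max(.data$score_margin),
              accessions = paste(unique(unlist(strsplit(.data$accessions, ";"))), collapse = ";"),
              .groups = "drop")
  if (nrow(pep) == 0) {
    return(tibble(group_id = character(), accessions = character(),
                  genes = character(), total_score = numeric(),
                  n_peptides = integer(), peptides = list()))
  }
  long <- pep |>
    mutate(accession = strsplit(.data$accessions, ";")) |>
    tidyr::unnest("accession")
  prot <- long |>
    group_by(.data$accession) |>
    summarise(peptide_set = list(sort(unique(.data$sequence))),
              total_score = sum(.data$best_score), .groups = "drop")

  # proteins with identical evidence collapse into one group
  prot <- prot |>
    mutate(set_key = purrr::map_chr(.data$peptide_set, paste, collapse = "|")) |>
    group_by(.data$set_key) |>
    summarise(accessions = list(sort(.data$accession)),
              peptide_set = .data$peptide_set[1],
              total_score = max(.data$total_score), .groups = "drop") |>
    arrange(desc(.data$total_score))

  # aggregate groups fully subsumed by a higher-scoring group: rows are
  # sorted by descending total score, so scan each group upwards for the
  # best-scoring superset and fold it in there
  keep <- rep(TRUE, nrow(prot))
  for (j in rev(seq_len(nrow(prot)))) {
    for (i in seq_len(j - 1L)) {
      if (!keep[i]) next
      if (all(prot$peptide_set[[j]] %in% prot$peptide_set[[i]])) {
        keep[j] <- FALSE
        prot$accessions[[i]] <- sort(union(prot$accessions[[i]], prot$accessions[[j]]))
        break
      }
    }
  }
  groups <- prot[keep, ]

  # gene-level merge
  if (!is.null(gene_map)) {
    genes_of <- function(accs) sort(unique(gene_map$gene[gene_map$accession %in% accs]))
    g <- purrr::map(groups$accessions, genes_of)
    merged <- rep(FALSE, nrow(groups))
    for (i in seq_len(nrow(groups))) {
      if (merged[i]) next
      for (j in seq_len(nrow(groups))) {
        if (j <= i || merged[j]) next
        if (length(intersect(g[[i]], g[[j]])) > 0) {
          groups$accessions[[i]] <- sort(union(groups$accessions[[i]], groups$accessions[[j]]))
          groups$peptide_set[[i]] <- sort(union(groups$peptide_set[[i]], groups$peptide_set[[j]]))
          groups$total_score[i] <- groups$total_score[i] + groups$total_score[j]
          g[[i]] <- sort(union(g[[i]], g[[j]]))
          merged[j] <- TRUE
        }
      }
    }
    groups <- groups[!merged, ]
    groups$genes <- purrr::map_chr(purrr::map(groups$accessions, genes_of),
                                   paste, collapse = ";")
  } else {
    groups$genes <- NA_character_
  }

  # anchor-peptide rule
  anchored <- purrr::map_lgl(groups$peptide_set, function(set) {
    rows <- pep[pep$sequence %in% set, ]
    any(nchar(rows$sequence) >= anchor_length & rows$score_margin >= anchor_margin)
  })
  groups <- groups[anchored, ]

  # uniqueness: peptide sequence present in exactly one group
  all_peps <- unlist(groups$peptide_set)
  unique_peps <- names(which(table(all_peps) == 1))
  groups |>
    mutate(
      group_id = purrr::map_chr(.data$accessions, ~ .x[1]),
      accessions = purrr::map_chr(.data$accessions, paste, collapse = ";"),
      n_peptides = lengths(.data$peptide_set),
      peptides = purrr::map(.data$peptide_set, function(set) {
        tibble(sequence = set,
               best_score = pep$best_score[match(set, pep$sequence)],
               unique = set %in% unique_peps)
      })
    ) |>
    select("group_id", "accessions", "genes", "total_score", "n_peptides", "peptides") |>
    arrange(desc(.data$total_score))
}

#' Long peptide-to-group map
#'
#' @param groups Output of [infer_protein_groups()].
#' @return Tibble (`group_id`, `sequence`, `best_score`, `unique`).
#' @export
protein_peptide_map <- function(groups) {
  groups |> select("group_id", "peptides") |> tidyr::unnest("peptides")
}

#' Picked-protein FDR
#'
#' Target-decoy protein FDR with pair picking: when both the target and the
#' decoy form of an accession were identified, only the higher-scoring member
#' of the pair enters the FDR computation (ties keep the target). This avoids
#' inflating the decoy count. FDR along descending score is monotonised into
#' q-values.
#'
#' @param protein_scores Tibble with `accession`, `score`, `is_decoy`; decoy
#'   accessions are the target accession with `decoy_prefix` prepended.
#' @param decoy_prefix Accession prefix marking decoys.
#' @return The picked subset with a `q_value` column.
#' @export
picked_protein_fdr <- function(protein_scores, decoy_prefix = "DECOY_") {
  bad <- protein_scores$is_decoy & !startsWith(protein_scores$accession, decoy_prefix)
  if (any(bad)) {
    abort(paste0("Decoy accession(s) without the '", decoy_prefix, "' prefix: ",
                 paste(head(protein_scores$accession[bad], 3), collapse = ", ")))
  }
  picked <- protein_scores |>
    mutate(base_accession = ifelse(.data$is_decoy,
                                   sub(paste0("^", decoy_prefix), "", .data$accession),
                                   .data$accession)) |>
    group_by(.data$base_accession) |>
    arrange(desc(.data$score), .data$is_decoy, .by_group = TRUE) |>
    slice(1) |>
    ungroup()
  picked |>
    mutate(q_value = .target_decoy_q(.data$score, .data$is_decoy)) |>
    select(-"base_accession")
}
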