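# Protein-complex turnover coherence and group comparisons.

#' Read a CORUM-style complex membership table
#'
#' Tab-separated with one row per complex and a semicolon-delimited subunit
#' column of Uniprot accessions. Standard CORUM headers (`ComplexID`,
#' `ComplexName`, `subunits(UniProt IDs)`) and the plain names used by this
#' package (`complex_id`, `complex_name`, `subunits`) are both accepted.
#'
#' @param path Path to the TSV file.
#' @return Long tibble (`complex_id`, `complex_name`, `accession`), members
#'   deduplicated within a complex.
#' @export
read_corum <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
  pick <- function(options) {
    hit <- intersect(options, names(raw))
    if (length(hit) == 0) abort(paste0("Missing complex-table column; expected one of: ",
                                       paste(options, collapse = ", ")))
    raw[[hit[1]]]
  }
  tibble(
    complex_id = as.character(pick(c("complex_id", "ComplexID"))),
    complex_name = as.character(pick(c("complex_name", "ComplexName"))),
    subunits = as.character(pick(c("subunits", "subunits(UniProt IDs)")))
  ) |>
    mutate(accession = strsplit(.data$subunits, ";")) |>
    select(-"subunits") |>
    tidyr::unnest("accession") |>
    mutate(accession = trimws(.data$accession)) |>
    distinct()
}

#' Within-complex half-life coherence test
#'
#' Computes the standard deviation of the log10 half-lives of the members of
#' every usable complex (at least `min_members` members with a measured
#' half-life), then builds a chance reference by repeatedly shuffling the
#' proteins associated with those complexes into random groups of the
#' original sizes and recomputing the SDs. Coherent turnover shows as
#' observed SDs stochastically smaller than shuffled SDs, assessed by a
#' one-sided Wilcoxon rank-sum test.
#'
#' @param half_lives Tibble (`accession`, `t_half` in hours).
#' @param complexes Long membership tibble (`complex_id`, `accession`),
#'   e.g. from [read_corum()].
#' @param n_shuffles Number of random reassignments.
#' @param min_members Minimum measured members per usable complex.
#' @param seed Optional integer seed (`set.seed` is called when given).
#'
#' @details Two p-values are reported. The primary `p_value` is the exact
#' permutation tail probability of the median within-complex SD under the
#' shuffle distribution, `(1 + #\{shuffle medians <= observed\}) / (n + 1)`:
#' it is uniformly distributed when membership carries no information about
#' half-life. The secondary `rank_sum_p` compares the observed SDs with the
#' pooled shuffled SDs by a one-sided Wilcoxon rank-sum test, matching how
#' such shuffle references are usually displayed; because both samples derive
#' from the same pooled half-lives this comparison is conservative and is
#' kept for presentation, not for calibrated inference.
#'
#' @return Object of class `complex_coherence`: observed per-complex SDs,
#'   the pooled shuffled SDs, both p-values, and bookkeeping fields.
#' @export
complex_coherence_test <- function(half_lives, complexes, n_shuffles = 1000,
                                   min_members = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  members <- complexes |>
    distinct(.data$complex_id, .data$accession) |>
    inner_join(half_lives, by = "accession") |>
    filter(!is.na(.data$t_half), .data$t_half > 0) |>
    mutate(log10_t_half = log10(.data$t_half))
  usable <- members |>
    count(.data$complex_id) |>
    filter(.data$n >= min_members)
  if (nrow(usable) < 2) abort("Need at least two complexes with enough measured members.")
  # canonical order makes the test invariant to the input row order
  members <- semi_join(members, usable, by = "complex_id") |>
    arrange(.data$complex_id, .data$accession)
  observed <- members |>
    group_by(.data$complex_id) |>
    summarise(n_members = n(), sd_log10 = sd(.data$log10_t_half), .groups = "drop")

  values <- members$log10_t_half
  sizes <- observed$n_members
  grp <- rep.int(seq_along(sizes), sizes)
  shuffled <- vapply(seq_len(n_shuffles), function(b) {
    perm <- sample(values)
    stopifnot(length(perm) == length(values)) # group sizes and multiset conserved
    vapply(split(perm, grp), sd, numeric(1))
  }, numeric(length(sizes)))
  shuffled_median <- apply(matrix(shuffled, nrow = length(sizes)), 2, median)
  shuffled <- as.numeric(shuffled)

  observed_median <- median(observed$sd_log10)
  p_perm <- (1 + sum(shuffled_median <= observed_median)) / (n_shuffles + 1)
  degenerate <- sd(c(observed$sd_log10, shuffled)) == 0
  rank_sum_p <- if (degenerate) 1 else
    suppressWarnings(wilcox.test(observed$sd_log10, shuffled, alternative = "less"))$p.value
  structure(
    list(observed = observed, shuffled_sd = shuffled,
         observed_median = observed_median, shuffled_median = shuffled_median,
         p_value = p_perm, rank_sum_p = rank_sum_p,
         degenerate = degenerate, n_shuffles = n_shuffles, seed = seed),
    class = "complex_coherence"
  )
}

#' @export
print.complex_coherence <- function(x, ...) {
  cat("<complex_coherence> ", nrow(x$observed), " complexes, ",
      x$n_shuffles, " shuffles\n", sep = "")
  cat("  median SD(log10 T1/2): observed ", signif(median(x$observed$sd_log10), 3),
      " vs shuffled ", signif(median(x$shuffled_sd), 3), "\n", sep = "")
  cat("  permutation p = ", format.pval(x$p_value, digits = 3),
      " (rank-sum p = ", format.pval(x$rank_sum_p, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.complex_coherence <- function(x, ...) x$observed

#' @export
glance.complex_coherence <- function(x, ...) {
  tibble(n_complexes = nrow(x$observed), n_shuffles = x$n_shuffles,
         median_observed_sd = median(x$observed$sd_log10),
         median_shuffled_sd = median(x$shuffled_sd),
         p_value = x$p_value, rank_sum_p = x$rank_sum_p)
}

#' Compare half-life distributions of two annotated subunit groups
#'
#' Two-sample Wilcoxon rank-sum test on log10 half-lives, as used to contrast
#' e.g. regulatory versus non-exchangeable core proteasome subunits, scaffold
#' versus peripheral nucleoporins, or cellular compartments.
#'
#' @param half_lives Tibble (`accession`, `t_half`).
#' @param group_a,group_b Character vectors of accessions.
#' @param alternative Passed to [wilcox.test()].
#' @return One-row tibble with `p_value`, `median_log10_diff` (A minus B),
#'   `direction` (sign of the difference), `n_a`, `n_b`.
#' @export
compare_annotated_groups <- function(half_lives, group_a, group_b,
                                     alternative = "two.sided") {
  val <- function(g) {
    v <- half_lives$t_half[half_lives$accession %in% g]
    log10(v[!is.na(v) & v > 0])
  }
  a <- val(group_a)
  b <- val(group_b)
  if (length(a) < 3 || length(b) < 3) {
    abort("Each group needs at least three measured proteins.")
  }
  p <- suppressWarnings(wilcox.test(a, b, alternative = alternative))$p.value
  diff <- median(a) - median(b)
  tibble(p_value = p, median_log10_diff = diff, direction = sign(diff),
         n_a = length(a), n_b = length(b))
}

#' Pairwise half-life RMSE between proteins across cell types
#'
#' For every pair of proteins measured in all compared cell types, computes
#' the root mean square error between their log10 half-life vectors, and
#' clusters the resulting distance matrix by average-linkage hierarchical
#' clustering. RMSE on fixed-length vectors is a metric, so the matrix is
#' symmetric with zero diagonal and obeys the triangle inequality.
#'
#' @param half_lives Tibble (`protein`, `cell_type`, `t_half`). Proteins with
#'   a missing cell-type value are dropped with a notice.
#' @return Object of class `halflife_rmse`: the RMSE `matrix`, the `hclust`
#'   tree and the deterministic `order` of leaves.
#' @export
pairwise_halflife_rmse <- function(half_lives) {
  wide <- half_lives |>
    filter(!is.na(.data$t_half), .data$t_half > 0) |>
    mutate(value = log10(.data$t_half)) |>
    select("protein", "cell_type", "value") |>
    tidyr::pivot_wider(names_from = "cell_type", values_from = "value")
  complete <- stats::complete.cases(wide)
  if (any(!complete)) {
    inform(paste0(sum(!complete), " protein(s) dropped: not measured in all cell types."))
  }
  wide <- wide[complete, ]
  if (nrow(wide) < 2) abort("Need at least two fully measured proteins.")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$protein
  k <- ncol(m)
  d <- as.matrix(stats::dist(m)) / sqrt(k)
  hc <- hclust(as.dist(d), method = "average")
  structure(list(rmse = d, hclust = hc, order = rownames(d)[hc$order]),
            class = "halflife_rmse")
}

#' @export
print.halflife_rmse <- function(x, ...) {
  cat("<halflife_rmse> ", nrow(x$rmse), " proteins, average-linkage tree\n", sep = "")
  invisible(x)
}

#' @export
tidy.halflife_rmse <- function(x, ...) {
  as_tibble(as.data.frame(as.table(x$rmse))) |>
    setNames(c("protein_a", "protein_b", "rmse")) |>
    mutate(across(c("protein_a", "protein_b"), as.character))
}
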