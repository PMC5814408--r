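# PSM condensing, FDR control, protein grouping and fold-change filters.

psm_row <- function(sequence, charge = 2L, modifications = "", score = 50,
                    run = "r1", scan = 1L, rt = 10, accessions = "P1",
                    is_decoy = FALSE) {
  tibble::tibble(run = run, scan = scan, rt = rt, sequence = sequence,
                 charge = charge, modifications = modifications,
                 score = score, accessions = accessions, is_decoy = is_decoy)
}

test_that("PSMs condense to one PCM per label-agnostic identity", {
  psms <- dplyr::bind_rows(
    psm_row("PEPTIDEK", score = 40, scan = 1L),
    psm_row("PEPTIDEK", score = 55, scan = 2L, modifications = "Heavy"),
    psm_row("PEPTIDEK", score = 30, scan = 3L, charge = 3L)
  )
  pcms <- condense_to_pcms(psms)
  expect_equal(nrow(pcms), 2L)   # light + heavy merge; charge 3 separate
  z2 <- pcms[pcms$charge == 2L, ]
  expect_equal(z2$best_score, 55)
  expect_equal(z2$scan, 2L)
  expect_equal(z2$n_psms, 2L)
})

test_that("score margins come from same-spectrum competitors", {
  psms <- dplyr::bind_rows(
    psm_row("AAAAAAK", score = 60, scan = 1L),
    psm_row("CCCCCCK", score = 45, scan = 1L),
    psm_row("DDDDDDK", score = 50, scan = 2L)
  )
  pcms <- condense_to_pcms(psms)
  expect_equal(pcms$score_margin[pcms$sequence == "AAAAAAK"], 15)
  # no competitor in the spectrum: margin is the score itself
  expect_equal(pcms$score_margin[pcms$sequence == "DDDDDDK"], 50)
})

test_that("q-values are monotone and match the exhaustive-threshold oracle", {
  set.seed(13)
  for (i in 1:5) {
    n <- 20
    tab <- tibble::tibble(
      accession = c(sprintf("P%02d", 1:12), sprintf("DECOY_P%02d", 1:8)),
      score = sample(seq(5, 100, by = 5), n),
      is_decoy = rep(c(FALSE, TRUE), c(12, 8))
    )
    out <- picked_protein_fdr(tab)
    expect_equal(out$q_value, oracle_picked_q(out$score, out$is_decoy))
    ord <- order(out$score, decreasing = TRUE)
    expect_true(all(diff(out$q_value[ord]) >= 0))
  }
})

test_that("picked-protein FDR keeps only the higher member of each pair", {
  tab <- tibble::tibble(
    accession = c("P1", "DECOY_P1", "P2", "DECOY_P3"),
    score = c(100, 50, 80, 60),
    is_decoy = c(FALSE, TRUE, FALSE, TRUE)
  )
  out <- picked_protein_fdr(tab)
  expect_false("DECOY_P1" %in% out$accession)   # lower-scoring decoy dropped
  expect_true("DECOY_P3" %in% out$accession)    # unopposed decoy survives
  # all decoys below all targets: every target q-value is zero
  low <- tibble::tibble(accession = c("P1", "P2", "DECOY_P4"),
                        score = c(90, 80, 10),
                        is_decoy = c(FALSE, FALSE, TRUE))
  outl <- picked_protein_fdr(low)
  expect_equal(outl$q_value[!outl$is_decoy], c(0, 0))

  bad <- tibble::tibble(accession = "REV_P1", score = 10, is_decoy = TRUE)
  expect_error(picked_protein_fdr(bad), "prefix")
})

test_that("protein grouping aggregates subsumed groups and demands an anchor", {
  mk <- function(seqs, accs, scores) {
    dplyr::bind_rows(purrr::map2(seqs, scores, function(s, sc) {
      psm_row(s, score = sc, scan = match(s, seqs), accessions = accs)
    }))
  }
  psms <- dplyr::bind_rows(
    mk(c("AAAAAAAK", "CCCCCCCK", "DDDDDDDK"), "PA", c(60, 55, 50)),
    mk(c("AAAAAAAK", "CCCCCCCK"), "PB", c(60, 55))
  )
  pcms <- peptide_fdr(condense_to_pcms(psms))
  groups <- infer_protein_groups(pcms)
  expect_equal(nrow(groups), 1L)                       # PB subsumed into PA
  expect_equal(groups$accessions, "PA;PB")

  # anchor margin below 10 points: group not reported
  weak <- dplyr::bind_rows(
    psm_row("EEEEEEEK", score = 50, scan = 1L, accessions = "PC"),
    psm_row("FFFFFFFK", score = 41, scan = 1L, accessions = "PC")
  )
  pcms_w <- peptide_fdr(condense_to_pcms(weak))
  expect_equal(nrow(infer_protein_groups(pcms_w)), 0L)

  # same gene id with disjoint peptides: one merged group
  two <- dplyr::bind_rows(
    psm_row("GGGGGGGK", score = 60, scan = 1L, accessions = "PD"),
    psm_row("HHHHHHHK", score = 60, scan = 2L, accessions = "PE")
  )
  pcms_two <- peptide_fdr(condense_to_pcms(two))
  gm <- tibble::tibble(accession = c("PD", "PE"), gene = "GENE1")
  merged <- infer_protein_groups(pcms_two, gene_map = gm)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$accessions, "PD;PE")
  # without the gene map they stay apart, and their peptides are unique
  apart <- infer_protein_groups(pcms_two)
  expect_equal(nrow(apart), 2L)
  expect_true(all(protein_peptide_map(apart)$unique))
})

quant_row <- function(sequence = "AAAAAAAK", best_score = 50, q_value = 0.001,
                      ratio_hl = 1, fit_light = 0.01, fit_heavy = 0.01,
                      prior_light = 0.05, prior_heavy = 0.05) {
  tibble::tibble(sequence = sequence, best_score = best_score,
                 q_value = q_value, ratio_hl = ratio_hl,
                 fit_light = fit_light, fit_heavy = fit_heavy,
                 prior_light = prior_light, prior_heavy = prior_heavy)
}

test_that("protein fold change is the median of surviving ratios", {
  q <- dplyr::bind_rows(quant_row(ratio_hl = 1), quant_row(ratio_hl = 2),
                        quant_row(ratio_hl = 3))
  expect_equal(protein_fold_change(q)$fold_change, 2)

  # undetermined ratios are excluded when a positive ratio exists
  q2 <- dplyr::bind_rows(quant_row(ratio_hl = 0.5), quant_row(ratio_hl = NA),
                         quant_row(ratio_hl = 1.5))
  res <- protein_fold_change(q2)
  expect_equal(res$fold_change, 1.0)
  expect_equal(res$n_peptides, 2L)

  # no surviving peptide with a ratio: undetermined
  expect_true(is.na(protein_fold_change(quant_row(ratio_hl = NA))$fold_change))
})

test_that("the filter cascade is the conjunction of its five conditions", {
  base <- quant_row(ratio_hl = 5)
  violations <- list(
    quant_row(best_score = 15),      # score must exceed 15
    quant_row(sequence = "AAAGK"),   # length below 6
    quant_row(q_value = 0.02),       # FDR above 1%
    quant_row(fit_heavy = 0.15),     # heavy-side fit too poor
    quant_row(prior_light = 0.25)    # light-side interference
  )
  for (bad in violations) {
    both <- dplyr::bind_rows(base, dplyr::mutate(bad, ratio_hl = 99))
    expect_equal(protein_fold_change(both)$fold_change, 5)
  }
  # boundary values pass: score just above, length 6, fits/priors at cutoff
  edge <- quant_row(sequence = "AAAGGK", best_score = 15.1, q_value = 0.01,
                    fit_light = 0.1, fit_heavy = 0.1,
                    prior_light = 0.2, prior_heavy = 0.2, ratio_hl = 7)
  expect_equal(protein_fold_change(edge)$fold_change, 7)
})

test_that("fold change is permutation- and median-duplication-invariant", {
  set.seed(3)
  q <- dplyr::bind_rows(lapply(c(0.4, 1.1, 2.0, 3.3, 8.0), function(r) {
    quant_row(ratio_hl = r)
  }))
  r0 <- protein_fold_change(q)$fold_change
  expect_equal(protein_fold_change(q[sample(5), ])$fold_change, r0)
  dup <- dplyr::bind_rows(q, quant_row(ratio_hl = r0))
  expect_equal(protein_fold_change(dup)$fold_change, r0)
})
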