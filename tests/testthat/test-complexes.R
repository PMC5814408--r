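# Complex coherence statistics, group comparisons, RMSE clustering and
# colour maps.

test_that("coherence shuffling conserves sizes and the half-life multiset", {
  sim <- simulate_complex_structure(n_complexes = 8, sizes = 6,
                                    within_sd = 0.2, between_spread = 0.2,
                                    seed = 41)
  res <- complex_coherence_test(sim$half_lives, sim$complexes,
                                n_shuffles = 50, seed = 41)
  expect_equal(length(res$shuffled_sd), 50 * 8)
  expect_equal(res$observed$n_members, rep(6L, 8))
  # determinism under a fixed seed
  res2 <- complex_coherence_test(sim$half_lives, sim$complexes,
                                 n_shuffles = 50, seed = 41)
  expect_identical(res$shuffled_sd, res2$shuffled_sd)
  expect_identical(res$p_value, res2$p_value)
})

test_that("planted coherence is detected and degenerate input gives p = 1", {
  sim <- simulate_complex_structure(n_complexes = 20, sizes = 6,
                                    within_sd = 0.05, between_spread = 0.5,
                                    seed = 7)
  res <- complex_coherence_test(sim$half_lives, sim$complexes,
                                n_shuffles = 1000, seed = 7)
  expect_lt(res$p_value, 0.001)
  expect_lt(res$rank_sum_p, 0.001)

  flat <- dplyr::mutate(sim$half_lives, t_half = 100)
  res_flat <- complex_coherence_test(flat, sim$complexes,
                                     n_shuffles = 50, seed = 1)
  expect_equal(res_flat$p_value, 1)
  expect_true(res_flat$degenerate)
})

test_that("the coherence test ignores complex order and half-life scale", {
  sim <- simulate_complex_structure(n_complexes = 10, sizes = 5,
                                    within_sd = 0.1, between_spread = 0.4,
                                    seed = 13)
  res <- complex_coherence_test(sim$half_lives, sim$complexes,
                                n_shuffles = 100, seed = 5)
  shuffled_rows <- sim$complexes[sample(nrow(sim$complexes)), ]
  res_perm <- complex_coherence_test(sim$half_lives, shuffled_rows,
                                     n_shuffles = 100, seed = 5)
  expect_equal(res_perm$p_value, res$p_value)
  # a scale factor is a shift in log10 and leaves every SD unchanged
  scaled <- dplyr::mutate(sim$half_lives, t_half = t_half * 10)
  res_scaled <- complex_coherence_test(scaled, sim$complexes,
                                       n_shuffles = 100, seed = 5)
  expect_equal(res_scaled$observed$sd_log10, res$observed$sd_log10)
  expect_equal(res_scaled$p_value, res$p_value)

  expect_error(
    complex_coherence_test(sim$half_lives[1:4, ], sim$complexes, n_shuffles = 10),
    "two complexes"
  )
})

test_that("annotated-group comparison matches exact rank-sum enumeration", {
  hl <- tibble::tibble(
    accession = c(paste0("A", 1:4), paste0("B", 1:4)),
    t_half = c(105, 230, 160, 318, 11, 25, 18, 30)
  )
  res <- compare_annotated_groups(hl, paste0("A", 1:4), paste0("B", 1:4),
                                  alternative = "less")
  expect_equal(res$p_value,
               oracle_ranksum_p_less(log10(hl$t_half[1:4]), log10(hl$t_half[5:8])))
  expect_equal(res$direction, 1)

  # complete separation: minimal attainable p for these group sizes
  sep <- compare_annotated_groups(hl, paste0("A", 1:4), paste0("B", 1:4),
                                  alternative = "greater")
  expect_equal(sep$p_value, 1 / choose(8, 4))

  ident <- compare_annotated_groups(
    dplyr::bind_rows(hl[1:4, ], dplyr::mutate(hl[1:4, ], accession = paste0("C", 1:4))),
    paste0("A", 1:4), paste0("C", 1:4)
  )
  expect_equal(ident$p_value, 1)

  expect_error(compare_annotated_groups(hl, paste0("A", 1:2), paste0("B", 1:4)),
               "three")
})

test_that("pairwise RMSE is a metric and clusters planted blocks", {
  hl <- tidyr::crossing(protein = c("p1", "p2"), cell_type = c("a", "b", "c", "d")) |>
    dplyr::mutate(t_half = 100)
  # identical vectors: zero distance; constant log10 offset delta: RMSE = delta
  hl$t_half[hl$protein == "p2"] <- 100 * 10^0.3
  r <- pairwise_halflife_rmse(hl)
  expect_equal(r$rmse["p1", "p1"], 0)
  expect_equal(r$rmse["p1", "p2"], 0.3, tolerance = 1e-12)

  set.seed(29)
  blocks <- tidyr::crossing(protein = sprintf("q%02d", 1:12),
                            cell_type = c("a", "b", "c", "d")) |>
    dplyr::mutate(block = ifelse(as.integer(substr(protein, 2, 3)) <= 6, 1, 2),
                  t_half = 10^(block + rnorm(dplyr::n(), 0, 0.05)))
  rb <- pairwise_halflife_rmse(dplyr::select(blocks, -block))
  expect_true(isSymmetric(rb$rmse))
  expect_equal(unname(diag(rb$rmse)), rep(0, 12))
  # triangle inequality
  m <- rb$rmse
  for (i in 1:12) for (j in 1:12) for (k in 1:12) {
    expect_lte(m[i, j], m[i, k] + m[k, j] + 1e-9)
  }
  cut <- stats::cutree(rb$hclust, k = 2)
  expect_equal(length(unique(cut[1:6])), 1L)
  expect_equal(length(unique(cut[7:12])), 1L)
  expect_false(cut[1] == cut[7])

  withmiss <- dplyr::filter(blocks, !(protein == "q01" & cell_type == "a"))
  expect_message(pairwise_halflife_rmse(dplyr::select(withmiss, -block)), "dropped")
})

test_that("colour maps interpolate, clip and flag undetermined subunits", {
  sub <- tidyr::crossing(accession = sprintf("s%02d", 1:10), replicate = 1:2) |>
    dplyr::mutate(t_half = rep(c(20, 40, 60, 80, 100, 120, 140, 160, 180, 2000), each = 2),
                  r_squared = 0.9)
  cm <- halflife_color_map(sub)
  expect_equal(nrow(cm), 10L)
  # the extreme outlier is clipped to the upper (blue) bound
  top <- cm[cm$unit == "s10", ]
  expect_true(top$clipped)
  expect_equal(top$colour, "#0000FF")

  # monotone: longer half-life is never redder
  redness <- function(hex) {
    rgb <- grDevices::col2rgb(hex)
    rgb["red", ] - rgb["blue", ]
  }
  ord <- order(cm$t_half)
  expect_true(all(diff(redness(cm$colour[ord])) <= 0))

  # all-equal half-lives map to the midpoint colour
  flat <- dplyr::mutate(sub, t_half = 50)
  cmf <- halflife_color_map(flat)
  expect_true(all(cmf$colour == "#FFFFFF"))

  # undetermined subunits are flagged and coloured distinctly
  holey <- dplyr::mutate(sub, t_half = ifelse(accession == "s05", NA, t_half))
  cmh <- halflife_color_map(holey)
  expect_false(cmh$determined[cmh$unit == "s05"])
  expect_equal(cmh$colour[cmh$unit == "s05"], "#00B200")

  # fused segments take the mean of their members
  seg <- halflife_color_map(sub, segments = list(seg1 = c("s01", "s02", "s03")))
  expect_equal(seg$t_half[seg$unit == "seg1"], mean(c(20, 40, 60)))
  expect_false(any(c("s01", "s02", "s03") %in% seg$unit))

  expect_error(halflife_color_map(sub[sub$accession == "s01", ]), "two subunits")
})

test_that("CORUM-style complex tables parse into long membership", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("ComplexID\tComplexName\tsubunits(UniProt IDs)",
               "1\tProteasome core\tP1;P2;P3",
               "2\tChaperonin\tP4;P5;P4"), path)
  tab <- read_corum(path)
  expect_equal(nrow(tab), 5L)   # duplicate member deduplicated
  expect_equal(tab$accession[tab$complex_id == "2"], c("P4", "P5"))
})
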