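# XIC extraction, peak detection, cluster assembly, envelope fitting and the
# prior-ion interference score.

test_that("XIC extraction sums matching centroids per scan", {
  target <- 500
  map <- tibble::tibble(
    scan = c(1L, 1L, 2L, 2L, 3L),
    rt = c(10.00, 10.00, 10.02, 10.02, 10.04),
    mz = c(500.000, 500.002, 500.001, 510, 500.000),
    intensity = c(100, 50, 80, 999, 60)
  )
  tr <- extract_xics(map, target, rt_center = 10.02, window = 1, tol_ppm = 7)
  expect_equal(tr$intensity, c(150, 80, 60))   # two in-tolerance centroids sum

  # 20 ppm away at 7 ppm tolerance: all-zero trace
  tr0 <- extract_xics(map, target * (1 + 20e-6), rt_center = 10.02, window = 1)
  expect_equal(tr0$intensity, c(0, 0, 0))

  unsorted <- map[c(5, 1, 2, 3, 4), ]
  unsorted$rt <- rev(unsorted$rt)
  expect_error(extract_xics(unsorted, target, 10.02), "sorted")
})

test_that("a sampled Gaussian yields one peak with analytic half-height bounds", {
  sigma <- 0.05
  rt <- seq(9.5, 10.5, by = 0.02)
  xic <- tibble::tibble(rt = rt, intensity = 1000 * exp(-(rt - 10)^2 / (2 * sigma^2)))
  pk <- detect_peaks(xic)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$apex_rt, rt[which.max(xic$intensity)])
  half_width <- sigma * sqrt(2 * log(2))
  expect_lt(abs(pk$left50 - (10 - half_width)), 0.02)
  expect_lt(abs(pk$right50 - (10 + half_width)), 0.02)
  expect_true(pk$left50 < pk$apex_rt && pk$apex_rt < pk$right50)

  expect_equal(nrow(detect_peaks(tibble::tibble(rt = rt, intensity = 0 * rt))), 0L)
})

test_that("well-separated Gaussians give two peaks with disjoint 50% windows", {
  sigma <- 0.05
  rt <- seq(9, 11, by = 0.02)
  xic <- tibble::tibble(rt = rt, intensity =
    1000 * exp(-(rt - 9.6)^2 / (2 * sigma^2)) +
    800 * exp(-(rt - 10.4)^2 / (2 * sigma^2)))
  pk <- detect_peaks(xic)
  expect_equal(nrow(pk), 2L)
  pk <- pk[order(pk$apex_rt), ]
  expect_lt(pk$right50[1], pk$left50[2])
})

test_that("cluster assembly honours the 50%-interval overlap and M1 rules", {
  base <- tibble::tibble(apex_rt = 10, apex_intensity = 100,
                         left50 = 9.95, right50 = 10.05)
  m0 <- dplyr::mutate(base, isotope = 0L)
  m1 <- dplyr::mutate(base, isotope = 1L, apex_intensity = 50)
  m2 <- dplyr::mutate(base, isotope = 2L, apex_intensity = 20)

  cl <- build_clusters(dplyr::bind_rows(m0, m1))
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$isotope, 0:1)

  # first 13C isotope missing: no candidate even though M2 overlaps
  expect_length(build_clusters(dplyr::bind_rows(m0, m2)), 0L)

  # disjoint M1 interval: not attached, so the candidate is removed
  m1_far <- dplyr::mutate(m1, apex_rt = 10.4, left50 = 10.35, right50 = 10.45)
  expect_length(build_clusters(dplyr::bind_rows(m0, m1_far)), 0L)
})

test_that("cluster candidates never lack the first 13C isotope", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(3:10, 1)
    peaks <- tibble::tibble(
      isotope = sample(0:4, n, replace = TRUE),
      apex_rt = runif(n, 9, 11),
      apex_intensity = runif(n, 10, 1000)
    )
    peaks$left50 <- peaks$apex_rt - runif(n, 0.02, 0.1)
    peaks$right50 <- peaks$apex_rt + runif(n, 0.02, 0.1)
    for (cl in build_clusters(peaks)) expect_true(1L %in% cl$isotope)
  }
})

test_that("envelope fitting is exact on proportional data and scale-equivariant", {
  env <- exact_envelope(composition_of_peptide("PEPTIDEK"), 2, 5)
  obs <- env$intensity * 1000
  f <- fit_cluster(obs, env)
  expect_equal(f$fitted_intensity, 1000, tolerance = 1e-9)
  expect_equal(f$fit_quality, 0, tolerance = 1e-12)

  obs_gap <- obs
  obs_gap[3] <- 0
  expect_gt(fit_cluster(obs_gap, env)$fit_quality, 0)

  # scaling observations scales the intensity and leaves the fit unchanged
  noisy <- obs * runif(5, 0.8, 1.2)
  f1 <- fit_cluster(noisy, env)
  f2 <- fit_cluster(noisy * 7.5, env)
  expect_equal(f2$fitted_intensity, 7.5 * f1$fitted_intensity, tolerance = 1e-9)
  expect_equal(f2$fit_quality, f1$fit_quality, tolerance = 1e-12)

  expect_true(is.na(fit_cluster(c(0, 0, 0, 0, 0), env)$fitted_intensity))
})

test_that("candidate selection matches a brute-force minimiser", {
  env <- exact_envelope(composition_of_peptide("PEPTIDEK"), 2, 5)
  set.seed(9)
  clusters <- lapply(1:6, function(i) {
    tibble::tibble(isotope = 0:4,
                   apex_rt = 10 + i / 100,
                   apex_intensity = env$intensity * 1000 * runif(5, 0.5, 1.5),
                   left50 = 9.9, right50 = 10.1)
  })
  best <- dynsilac:::.best_xic_fit(clusters, env)
  manual <- lapply(clusters, function(cl) fit_cluster(cl$apex_intensity, env))
  expect_equal(best$fit_quality, min(vapply(manual, `[[`, numeric(1), "fit_quality")))
})

test_that("clean simulated SILAC pairs are quantified to the true ratio", {
  sim <- simulate_ms1_map(sim_scenario(n_peptides = 6, ratio_hl = 0.25,
                                       noise_sigma = 0, seed = 21))
  q <- quantify_pcms(sim$pcms, sim$ms1)
  expect_true(all(abs(q$ratio_hl / 0.25 - 1) < 0.02))
  expect_true(all(q$fit_light <= 0.1 & q$fit_heavy <= 0.1))
  expect_true(all(q$prior_light < 0.2 & q$prior_heavy < 0.2))
})

test_that("an absent heavy signal leaves the ratio undetermined", {
  sim <- simulate_ms1_map(sim_scenario(n_peptides = 3, ratio_hl = 0,
                                       noise_sigma = 0, seed = 22))
  q <- quantify_pcms(sim$pcms, sim$ms1)
  expect_true(all(is.na(q$heavy_intensity)))
  expect_true(all(is.na(q$ratio_hl)))
  expect_true(all(q$light_intensity > 0))
})

test_that("a poor chromatographic fit falls back to survey-scan clusters", {
  seqs <- "LSEGLAEYK"
  comp <- composition_of_peptide(seqs)
  env <- exact_envelope(comp, 2)
  clean <- make_gaussian_map(list(env$mz), list(1000 * env$intensity), rt0 = 10)
  # corrupt the M1 XIC away from the apex: two flanking blobs that overlap
  # the monoisotopic 50% interval distort the chromatographic cluster but
  # leave the apex scan itself clean
  blob <- dplyr::filter(clean, abs(rt - 10) > 0.03, abs(rt - 10) < 0.08)
  blob <- dplyr::filter(blob, abs(mz - env$mz[2]) < 1e-6)
  blob$intensity <- 5e4
  corrupted <- dplyr::arrange(dplyr::bind_rows(clean, blob), scan, mz)
  pcm <- list(sequence = seqs, charge = 2L, modifications = "", rt = 10)
  q <- quantify_pcm(pcm, corrupted)
  expect_true(q$source_light %in% c("AS", "PS"))
  expect_lte(q$fit_light, 0.1)
})

test_that("the prior-ion ratio flags a co-eluting cluster one neutron below", {
  sim <- simulate_ms1_map(sim_scenario(n_peptides = 12, ratio_hl = 0.5,
                                       noise_sigma = 0, seed = 31,
                                       interference_fraction = 0.5,
                                       interference_intensity = 2))
  q <- quantify_pcms(sim$pcms, sim$ms1)
  flagged <- q$prior_heavy > 0.2
  expect_true(all(flagged[sim$truth$interfered]))
  # clean peptides stay below the threshold
  expect_true(all(q$prior_heavy[!sim$truth$interfered] <= 0.2))
  # and clean light channels report (near) zero
  expect_true(all(q$prior_light[!sim$truth$interfered] < 0.05))
})

test_that("prior ion ratio is the prior intensity over the fitted cluster sum", {
  seqs <- "LSEGLAEYK"
  env <- exact_envelope(composition_of_peptide(seqs), 2)
  prior_mz <- env$mz[1] - 1.0033548378 / 2
  amp <- 1000
  clean <- make_gaussian_map(list(c(prior_mz, env$mz)),
                             list(c(amp, amp * env$intensity)), rt0 = 10)
  pcm <- list(sequence = seqs, charge = 2L, modifications = "", rt = 10)
  q <- quantify_pcm(pcm, clean)
  # prior peak amplitude equals the summed fitted intensities -> ratio 1
  expect_equal(q$prior_light, 1, tolerance = 0.05)
})
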