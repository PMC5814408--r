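# Synthetic ground-truthed data for every pipeline stage.
#
# The generators emulate the study design: SILAC pairs eluting as Gaussian
# chromatographic peaks whose centroid intensities follow the theoretical
# envelope, optional co-eluting interferers one neutron below the target,
# fold-change time courses r(t) = exp(k * t) - 1 from known half-lives, and
# planted complex structures. Everything is deterministic under a fixed seed.

#' Random tryptic peptide sequences
#'
#' Uniform residues with a C-terminal K or R, as produced by tryptic
#' digestion.
#'
#' @param n Number of peptides.
#' @param length_range Min/max peptide length (residues, incl. terminus).
#' @param seed Optional integer seed.
#' @return Character vector of unique sequences.
#' @export
random_tryptic_peptides <- function(n, length_range = c(7, 18), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  alphabet <- setdiff(names(.residue_formulas), c("K", "R"))
  out <- character(0)
  while (length(out) < n) {
    len <- sample(length_range[1]:length_range[2], 1)
    body <- paste(sample(alphabet, len - 1, replace = TRUE), collapse = "")
    out <- unique(c(out, paste0(body, sample(c("K", "R"), 1))))
  }
  out[seq_len(n)]
}

#' Simulation scenario for an MS1 map
#'
#' Bundles the peptides, mixing design and noise/interference model used by
#' [simulate_ms1_map()]. The default mixing ratio of 1 corresponds to the 1:1
#' heavy:light mixture of the evaluation design; 1/9 and 1/49 reproduce the
#' 1:9 and 1:49 dilutions.
#'
#' @param n_peptides Number of SILAC pairs.
#' @param ratio_hl Heavy/light mixing ratio(s), recycled over peptides.
#' @param intensity Light-channel apex amplitude(s) (counts).
#' @param charge Charge state(s), recycled.
#' @param sigma_rt Chromatographic Gaussian width (minutes).
#' @param scan_interval Survey-scan interval (seconds).
#' @param noise_sigma SD of multiplicative log-normal noise on centroid
#'   intensities (0 = noise free).
#' @param interference_fraction Fraction of peptides given a co-eluting
#'   interfering cluster whose monoisotopic peak sits one neutron below the
#'   target's.
#' @param interference_intensity Interferer apex amplitude relative to the
#'   interfered label's amplitude.
#' @param interference_target Label state receiving the interferer.
#' @param seed Integer seed consumed when the map is generated.
#' @return List of class `sim_scenario`.
#' @export
sim_scenario <- function(n_peptides = 50, ratio_hl = 1, intensity = 1e6,
                         charge = 2L, sigma_rt = 0.05, scan_interval = 1.2,
                         noise_sigma = 0, interference_fraction = 0,
                         interference_intensity = 2,
                         interference_target = c("heavy", "light"),
                         seed = 1L) {
  structure(
    list(n_peptides = n_peptides, ratio_hl = ratio_hl, intensity = intensity,
         charge = charge, sigma_rt = sigma_rt, scan_interval = scan_interval,
         noise_sigma = noise_sigma,
         interference_fraction = interference_fraction,
         interference_intensity = interference_intensity,
         interference_target = match.arg(interference_target),
         seed = as.integer(seed)),
    class = c("sim_scenario", "list")
  )
}

# All m/z positions (both label ladders plus the prior-ion slot) a peptide
# can occupy, used to keep co-eluting simulated peptides from colliding.
.ladder_positions <- function(sequence, charge) {
  mzs <- unlist(lapply(c("light", "heavy"), function(lab) {
    exact_envelope(composition_of_peptide(sequence, label = lab), charge)$mz
  }))
  c(mzs, min(mzs) - .neutron_mass / charge)
}

# Draw n tryptic peptides whose isotope ladders stay > min_ppm apart from
# those of co-eluting neighbours (|delta rt| <= rt_guard), so that unplanted
# interference cannot arise. Consumes the current RNG stream.
.collision_free_peptides <- function(n, charge, rt, rt_guard = 0.45,
                                     min_ppm = 30, length_range = c(7, 18)) {
  charge <- rep_len(charge, n)
  sequences <- character(n)
  ladders <- vector("list", n)
  for (i in seq_len(n)) {
    neighbours <- which(abs(rt[seq_len(i - 1)] - rt[i]) <= rt_guard)
    near <- unlist(ladders[neighbours])
    for (try in 1:100) {
      cand <- random_tryptic_peptides(1, length_range)
      if (cand %in% sequences) next
      pos <- .ladder_positions(cand, charge[i])
      if (length(near) == 0 ||
          min(vapply(pos, function(m) min(abs(near - m) / m) * 1e6, numeric(1))) > min_ppm) {
        sequences[i] <- cand
        ladders[[i]] <- pos
        break
      }
    }
    if (!nzchar(sequences[i])) {
      abort("Could not place a collision-free peptide; lower the density.")
    }
  }
  sequences
}

# Gaussian elution profile of one isotope ladder over the scan grid.
.elute_ladder <- function(scans, mz, amplitude, rt0, sigma) {
  near <- which(abs(scans$rt - rt0) <= 5 * sigma)
  if (length(near) == 0 || all(amplitude <= 0)) return(NULL)
  g <- exp(-(scans$rt[near] - rt0)^2 / (2 * sigma^2))
  tibble(
    scan = rep(scans$scan[near], each = length(mz)),
    rt = rep(scans$rt[near], each = length(mz)),
    mz = rep(mz, times = length(near)),
    intensity = as.numeric(outer(amplitude, g))
  )
}

#' Simulate a centroided MS1 map of SILAC pairs
#'
#' Each peptide elutes as a Gaussian peak; in every survey scan its light and
#' heavy isotope ladders appear as centroids whose intensities follow the
#' exact theoretical envelope scaled by the channel amplitude. A chosen
#' fraction of peptides additionally receives a co-eluting interferer (an
#' averagine-composition envelope of the same charge) whose monoisotopic
#' peak lies one neutron below the target's, the situation the prior-ion
#' ratio is designed to flag.
#'
#' @param scenario A [sim_scenario()].
#' @return List with `ms1` (centroid tibble: `scan`, `rt`, `mz`,
#'   `intensity`), `truth` (per-peptide ground truth incl. `ratio_hl` and
#'   `interfered`), and `pcms` (the matching identification table for
#'   [quantify_pcms()]).
#' @export
simulate_ms1_map <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(scenario$seed)
  n <- scenario$n_peptides
  rts <- 5 + (seq_len(n) - 1) * 0.12
  peptides <- tibble(
    sequence = .collision_free_peptides(n, scenario$charge, rts),
    charge = as.integer(rep_len(scenario$charge, n)),
    rt = rts,
    light_amplitude = rep_len(scenario$intensity, n),
    ratio_hl = rep_len(scenario$ratio_hl, n)
  )
  n_interfere <- round(scenario$interference_fraction * n)
  interfered_idx <- if (n_interfere > 0) sort(sample.int(n, n_interfere)) else integer(0)
  peptides$interfered <- seq_len(n) %in% interfered_idx

  rt_range <- range(peptides$rt)
  step <- scenario$scan_interval / 60
  scan_rt <- seq(rt_range[1] - 0.6, rt_range[2] + 0.6, by = step)
  scans <- tibble(scan = seq_along(scan_rt), rt = scan_rt)

  rows <- purrr::map(seq_len(n), function(i) {
    p <- peptides[i, ]
    per_label <- purrr::map(c(light = "light", heavy = "heavy"), function(lab) {
      comp <- composition_of_peptide(p$sequence, label = lab)
      env <- exact_envelope(comp, p$charge)
      amp <- if (lab == "light") p$light_amplitude else p$light_amplitude * p$ratio_hl
      main <- .elute_ladder(scans, env$mz, amp * env$intensity, p$rt, scenario$sigma_rt)
      if (p$interfered && lab == scenario$interference_target) {
        prior_mz <- env$mz[1] - .neutron_mass / p$charge
        mass <- prior_mz * p$charge - p$charge * .proton_mass
        ienv <- averagine_envelope(mass, p$charge)
        iamp <- scenario$interference_intensity * amp
        extra <- .elute_ladder(scans, ienv$mz, iamp * ienv$intensity,
                               p$rt + 0.01, scenario$sigma_rt)
        main <- bind_rows(main, extra)
      }
      main
    })
    bind_rows(per_label)
  })
  ms1 <- bind_rows(rows) |>
    filter(.data$intensity > 0) |>
    arrange(.data$scan, .data$mz)
  if (scenario$noise_sigma > 0) {
    ms1$intensity <- ms1$intensity * exp(stats::rnorm(nrow(ms1), 0, scenario$noise_sigma))
  }
  pcms <- peptides |>
    mutate(modifications = "") |>
    select("sequence", "charge", "modifications", "rt")
  list(ms1 = ms1, truth = peptides, pcms = pcms)
}

#' Simulate fold-change time courses from known half-lives
#'
#' `r(t) = exp(k * t) - 1` with `k = log(2) / T_half`, plus multiplicative
#' log-normal noise on the ratio itself (`r * exp(e)`, `e ~ N(0, sigma^2)`),
#' which keeps fold changes non-negative however slow the turnover.
#'
#' @param true_half_lives Named numeric vector (protein -> half-life, hours).
#' @param time_points Sampling times (hours).
#' @param noise_sigma SD of the log-normal noise (0 = noise free).
#' @param n_peptides Peptide counts per time point (recycled), driving the QC
#'   label downstream.
#' @param seed Optional integer seed.
#' @return Tibble (`protein`, `time_h`, `ratio`, `n_peptides`).
#' @export
simulate_time_course <- function(true_half_lives, time_points = c(7, 11, 24, 34),
                                 noise_sigma = 0.05, n_peptides = 3L, seed = NULL) {
  stopifnot(all(true_half_lives > 0))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(names(true_half_lives))) {
    names(true_half_lives) <- sprintf("protein_%04d", seq_along(true_half_lives))
  }
  tidyr::crossing(protein = names(true_half_lives), time_h = time_points) |>
    mutate(
      t_half = unname(true_half_lives[.data$protein]),
      k = log(2) / .data$t_half,
      ratio = (exp(.data$k * .data$time_h) - 1) *
        exp(stats::rnorm(n(), 0, noise_sigma)),
      n_peptides = rep_len(as.integer(n_peptides), n())
    ) |>
    select("protein", "time_h", "ratio", "n_peptides")
}

#' Simulate a planted protein-complex structure
#'
#' Members scatter with SD `within_sd` (log10 hours) around their complex
#' centre; `between_spread` is the total SD of the log10 half-life
#' distribution, so centres are drawn with SD
#' `sqrt(between_spread^2 - within_sd^2)`. Setting `within_sd` equal to
#' `between_spread` therefore collapses all centres onto one value —
#' half-lives carry no membership information and the coherence test sees a
#' null; `within_sd` well below `between_spread` plants coherent structure.
#'
#' @param n_complexes Number of complexes.
#' @param sizes Members per complex (recycled).
#' @param within_sd Within-complex SD of log10 half-lives.
#' @param between_spread Total SD of log10 half-lives across all proteins
#'   (must be at least `within_sd`).
#' @param center_log10 Grand mean of log10 half-life (hours).
#' @param seed Optional integer seed.
#' @return List with `half_lives` (tibble `accession`, `t_half`) and
#'   `complexes` (tibble `complex_id`, `accession`).
#' @export
simulate_complex_structure <- function(n_complexes = 20, sizes = 6,
                                       within_sd = 0.05, between_spread = 0.5,
                                       center_log10 = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sizes <- rep_len(sizes, n_complexes)
  center_sd <- sqrt(max(0, between_spread^2 - within_sd^2))
  centers <- stats::rnorm(n_complexes, center_log10, center_sd)
  members <- purrr::map_dfr(seq_len(n_complexes), function(i) {
    tibble(
      complex_id = sprintf("CPX%03d", i),
      accession = sprintf("SIM%03d_%02d", i, seq_len(sizes[i])),
      t_half = 10^stats::rnorm(sizes[i], centers[i], within_sd)
    )
  })
  list(half_lives = select(members, "accession", "t_half"),
       complexes = select(members, "complex_id", "accession"))
}

#' Simulate a complete dynamic SILAC experiment
#'
#' Builds, for every replicate and time point, an MS1 map whose SILAC pair
#' ratios follow each protein's decay curve, plus the matching PSM table
#' (with decoys) and the experiment design table — the full input set of
#' [run_pipeline()], with ground truth attached.
#'
#' @param n_proteins Number of simulated proteins.
#' @param peptides_per_protein Unique peptides per protein.
#' @param half_life_range Half-lives drawn log-uniformly from this range
#'   (hours).
#' @param time_points Pulse time points (hours).
#' @param replicates Number of biological replicates.
#' @param intensity Light-channel apex amplitude.
#' @param noise_sigma Centroid intensity noise SD.
#' @param seed Integer seed.
#' @return List with `psms`, `spectra` (named list of MS1 maps per run),
#'   `design` (tibble `run`, `replicate`, `time_h`), `truth` (tibble
#'   `protein`, `t_half`), `gene_map`.
#' @export
simulate_experiment <- function(n_proteins = 12, peptides_per_protein = 3,
                                half_life_range = c(20, 500),
                                time_points = c(7, 11, 24, 34), replicates = 2,
                                intensity = 1e6, noise_sigma = 0.02, seed = 1L) {
  set.seed(seed)
  proteins <- sprintf("P%05d", seq_len(n_proteins))
  t_half <- 10^stats::runif(n_proteins, log10(half_life_range[1]), log10(half_life_range[2]))
  truth <- tibble(protein = proteins, t_half = t_half)
  n_pep <- n_proteins * peptides_per_protein
  pep_rts <- 5 + (seq_len(n_pep) - 1) * 0.12
  peptide_tab <- tibble(
    protein = rep(proteins, each = peptides_per_protein),
    sequence = .collision_free_peptides(n_pep, 2L, pep_rts),
    charge = 2L,
    rt = pep_rts,
    score = stats::runif(n_pep, 40, 90)
  )
  decoys <- tibble(
    protein = paste0("DECOY_", rep(proteins, each = 1)),
    sequence = random_tryptic_peptides(n_proteins, seed = NULL),
    charge = 2L,
    rt = 5, score = stats::runif(n_proteins, 2, 14)
  )

  design <- tidyr::crossing(replicate = seq_len(replicates), time_h = time_points) |>
    mutate(run = sprintf("rep%d_t%02dh", .data$replicate, .data$time_h))
  map_seeds <- sample.int(1e6, nrow(design))

  spectra <- list()
  psm_rows <- list()
  for (i in seq_len(nrow(design))) {
    t_i <- design$time_h[i]
    run <- design$run[i]
    ratios <- exp(log(2) / truth$t_half * t_i) - 1
    pep_ratio <- ratios[match(peptide_tab$protein, truth$protein)]
    scen <- sim_scenario(
      n_peptides = nrow(peptide_tab), ratio_hl = pep_ratio,
      intensity = intensity, charge = 2L, noise_sigma = noise_sigma,
      seed = map_seeds[i]
    )
    spectra[[run]] <- .resimulate_with_sequences(scen, peptide_tab)
    psm_rows[[run]] <- bind_rows(
      peptide_tab |> mutate(is_decoy = FALSE, accessions = .data$protein),
      decoys |> mutate(is_decoy = TRUE, accessions = .data$protein)
    ) |>
      mutate(run = run, scan = seq_len(n()), modifications = "") |>
      select("run", "scan", "rt", "sequence", "charge", "modifications",
             "score", "accessions", "is_decoy")
  }
  list(psms = bind_rows(psm_rows), spectra = spectra, design = design,
       truth = truth,
       gene_map = tibble(accession = proteins, gene = paste0("GENE_", proteins)))
}

# Internal: simulate a map for a fixed peptide table (sequences, charges,
# RTs) with the per-peptide ratios carried in the scenario.
.resimulate_with_sequences <- function(scenario, peptide_tab) {
  set.seed(scenario$seed)
  n <- nrow(peptide_tab)
  peptides <- peptide_tab |>
    select("sequence", "charge", "rt") |>
    mutate(light_amplitude = rep_len(scenario$intensity, n),
           ratio_hl = rep_len(scenario$ratio_hl, n))
  rt_range <- range(peptides$rt)
  step <- scenario$scan_interval / 60
  scan_rt <- seq(rt_range[1] - 0.6, rt_range[2] + 0.6, by = step)
  scans <- tibble(scan = seq_along(scan_rt), rt = scan_rt)
  rows <- purrr::map(seq_len(n), function(i) {
    p <- peptides[i, ]
    bind_rows(purrr::map(c("light", "heavy"), function(lab) {
      comp <- composition_of_peptide(p$sequence, label = lab)
      env <- exact_envelope(comp, p$charge)
      amp <- if (lab == "light") p$light_amplitude else p$light_amplitude * p$ratio_hl
      .elute_ladder(scans, env$mz, amp * env$intensity, p$rt, scenario$sigma_rt)
    }))
  })
  ms1 <- bind_rows(rows) |>
    filter(.data$intensity > 0) |>
    arrange(.data$scan, .data$mz)
  if (scenario$noise_sigma > 0) {
    ms1$intensity <- ms1$intensity * exp(stats::rnorm(nrow(ms1), 0, scenario$noise_sigma))
  }
  ms1
}
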