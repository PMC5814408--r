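# dynsilac

Protein turnover analysis for **dynamic SILAC** proteomics in non-dividing
cells: peptide ion intensity-based quantification of MS1 SILAC pairs,
closed-form half-life estimation, and protein-complex turnover statistics —
with a fully seeded synthetic-data generator so every stage can be exercised
and validated end to end.

## The problem

In a pulse-labelling (dynamic SILAC) experiment, cells are switched to medium
with heavy lysine (+8.014199 Da) and arginine (+10.008269 Da). Newly
synthesised protein appears in the heavy channel while pre-existing protein
stays light, so the heavy/light ratio over time encodes turnover. In
non-dividing primary cells, long-lived proteins incorporate very little label
during a feasible pulse: the heavy signal is tiny, and small quantification
errors translate into large half-life errors. `dynsilac` implements a
quantification strategy built for exactly this regime:

- **Exact isotopic envelopes.** The theoretical envelope of every identified
  peptide is computed from its exact elemental composition (label-substituted
  ¹³C/¹⁵N atoms treated as fixed), not from the mass-only averagine
  approximation, and fitted to isotope-cluster candidates by least squares.
  The fit residual (on unit-normalised vectors) doubles as a quality score.
- **Prior-ion interference detection.** A peak one neutron *below* the
  monoisotopic ion is essentially absent for a clean peptide, so the ratio of
  that "prior ion" intensity to the fitted cluster intensity flags co-eluting
  interfering envelopes. Peptides with prior-ion ratio > 0.2 are excluded.
- **Half-life from the pulse model.** With fold change `r(t) = exp(k t) − 1`,
  the decay-rate constant is the through-origin least-squares slope

      k_dp = Σ log(r_ti + 1) · t_i / Σ t_i² ,   T½ = log 2 / k_dp

  with the squared Pearson correlation of `t` vs `log(r+1)` as fit quality
  and good/weak/poor QC labels from time-point and peptide coverage.
- **Complex coherence.** Whether subunits of annotated complexes (CORUM-style
  tables) turn over coherently is tested by comparing within-complex
  standard deviations of log10 half-lives against size-preserving random
  reshuffles of the member proteins.

The pipeline in between — PSM condensing into PCMs (peptide / charge /
modification groups), target-decoy peptide FDR, protein-group inference with
anchor peptides and gene-level merging, picked-protein FDR, and the
five-filter cascade (score > 15, length ≥ 6, FDR ≤ 1%, both-label fit ≤ 0.1,
both-label prior-ion ratio ≤ 0.2) feeding median peptide ratios into protein
fold changes — is implemented in full.

## Worked example

Theoretical envelope of a heavy-labelled tryptic peptide at charge 2:

```r
library(dynsilac)
exact_envelope(composition_of_peptide("LVNELTEFAK", label = "heavy"), charge = 2)
#> # A tibble: 6 × 3
#>   isotope    mz intensity
#>     <int> <dbl>     <dbl>
#> 1       0  586.  0.553
#> 2       1  587.  0.310
#> 3       2  587.  0.105
#> 4       3  588.  0.0262
#> 5       4  588.  0.00535
#> 6       5  589.  0.000929
```

Simulate an MS1 map of SILAC pairs mixed 1:4 (heavy:light) with 2% intensity
noise, and quantify it:

```r
sim <- simulate_ms1_map(sim_scenario(n_peptides = 5, ratio_hl = 0.25,
                                     noise_sigma = 0.02, seed = 42))
quantify_pcms(sim$pcms, sim$ms1) |>
  dplyr::select(sequence, light_intensity, heavy_intensity, ratio_hl, fit_light, fit_heavy)
#> # A tibble: 5 × 6
#>   sequence       light_intensity heavy_intensity ratio_hl  fit_light fit_heavy
#> 1 VGNPWYR                998217.         246912.    0.247 0.00000438 0.000115
#> 2 CPVMWHSIPVEVAR         995643.         245237.    0.246 0.000151   0.0000881
#> 3 SGNDHLPPWEVPAR        1011435.         253586.    0.251 0.0000169  0.0000502
#> 4 SYWTTASR              1008804.         247410.    0.245 0.00000455 0.0000358
#> 5 ATNLVGYCPER            999825.         240338.    0.240 0.0000234  0.000114
```

Every recovered ratio sits within ~4% of the true 0.25 under noise, and the
fit residuals are far below the 0.1 acceptance threshold.

Half-lives from fold-change time courses (4 pulse time points, 5% noise):

```r
tc <- simulate_time_course(c(JAK3 = 10, LMNB1 = 1550, HIST1H1C = 2242),
                           noise_sigma = 0.05, seed = 42)
fit_turnover(tc)
#> # A tibble: 3 × 6
#>   protein      k_dp  t_half r_squared qc    n_points
#> 1 HIST1H1C 0.000317 2187.       0.999 good         4
#> 2 JAK3     0.0700      9.90     0.999 good         4
#> 3 LMNB1    0.000490 1414.       0.997 good         4
```

A fast protein (10 h) is recovered almost exactly; the 2242 h histone-like
protein — which gains only ~1% heavy signal over the whole pulse — is still
recovered within 3% on the log10 scale. Coherent within-complex turnover is
detected against a shuffle reference:

```r
cx <- simulate_complex_structure(n_complexes = 20, sizes = 6,
                                 within_sd = 0.05, between_spread = 0.5, seed = 42)
complex_coherence_test(cx$half_lives, cx$complexes, n_shuffles = 1000, seed = 42)
#> <complex_coherence> 20 complexes, 1000 shuffles
#>   median SD(log10 T1/2): observed 0.0455 vs shuffled 0.611
#>   permutation p = 0.000999 (rank-sum p = 5e-15)
```

Fitted objects support `tidy()`, `glance()` and `autoplot()`; the full
pipeline (`run_pipeline()`) ties the stages together and
`inst/cli/dynsilac.R` exposes them as shell subcommands
(`envelope`, `simulate`, `quantify`, `halflife`, `complexes`, `run`).

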