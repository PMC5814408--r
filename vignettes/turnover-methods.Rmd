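---
title: "Models and methods behind dynsilac"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dynsilac}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynsilac)
```

`dynsilac` quantifies protein turnover from pulse (dynamic) SILAC
experiments in non-dividing cells. This vignette explains the models the
package implements, the assumptions behind them, the tunable parameters and
their defaults, what the synthetic-data generators do and do not emulate,
and the numerical choices made where the design was genuinely open.

## 1. Isotopic envelopes from exact compositions

A peptide's MS1 signal is spread over an isotope ladder spaced by one
neutron mass over charge (1.0033548 / z Th, the ^13^C–^12^C difference).
The relative intensities of that ladder are fully determined by the
peptide's elemental composition and the natural isotope abundances of
C, H, N, O and S. `composition_of_peptide()` sums residue formulas plus one
water, applies modification deltas (carbamidomethyl-C, oxidation-M,
N-terminal acetyl), and — for the heavy SILAC state — marks the substituted
atoms (6 × ^13^C + 2 × ^15^N per lysine, 6 × ^13^C + 4 × ^15^N per
arginine) as *fixed heavy*: they shift the monoisotopic mass by +8.014199 Da
(K) or +10.008269 Da (R) and are excluded from the abundance convolution,
because the label is (ideally) isotopically pure.

`exact_envelope()` convolves the per-atom isotope-offset distributions of
all free atoms. The implementation uses binary exponentiation of truncated
convolutions; truncation to the first *L* offsets during the convolution is
exact for those offsets because the distributions are non-negative and
offsets only add. The abundance table is the IUPAC/CIAAW representative set,
stored in `R/constants.R` with provenance noted there. The test suite pins
the convolution against an independent exhaustive isotopologue enumeration
to 10^-9^.

Parameters and defaults:

* **Envelope length** (`n_isotopes`, default automatic): the smallest
  number of peaks reaching 0.999 cumulative un-truncated probability,
  capped at 8. Tryptic peptides below ~3 kDa rarely need more; exactly-zero
  tail entries are dropped.
* **Averagine baseline** (`averagine_envelope()`): the standard
  average-amino-acid unit (C~4.94~ H~7.76~ N~1.36~ O~1.48~ S~0.042~) scaled
  to the target mass with hydrogen balancing. It exists as a comparison
  baseline only — the package's own quantification always uses the exact
  composition, which matters most for composition outliers such as
  cysteine-rich peptides.

## 2. MS1 quantification

For each PCM (peptide / charge / modification group, the quantification
unit condensed from PSMs) and each label state:

1. XICs are extracted at every envelope m/z within ±`tol_ppm` (default
   7 ppm) over a `xic_window` (default 1 min) around the identification RT.
   The search engine's precursor tolerance is a different setting; XIC
   extraction on centroided high-resolution data warrants the tighter
   default, and both are configurable in `run_config()`.
2. Chromatographic peaks are detected per XIC: 3-point moving-average
   smoothing, local maxima above `max(min_intensity, 3 × median trace)`,
   and 50%-apex boundaries by linear interpolation on the raw trace. This
   is the simplest reproducible scheme that honours the 50%-apex overlap
   rule used downstream; the apex intensity is read from the raw trace.
3. Candidate isotope clusters anchor on each monoisotopic peak and attach,
   per isotope index, at most one peak whose 50%-apex interval overlaps the
   monoisotopic peak's interval (largest overlap wins, ties by apex
   proximity). Candidates missing the first ^13^C isotope are discarded —
   a genuine peptide at detectable intensity always shows its M+1.
4. The theoretical envelope is fitted to the candidate's apex intensities
   by least squares. The *fitted intensity* is the scale factor (linear in
   signal); the *fit quality* is the residual sum of squares after both
   vectors are normalised to unit sum, with missing isotopes counted as
   zero — making the 0.1 acceptance threshold dimensionless and
   transferable across intensities.
5. If the best chromatographic fit exceeds 0.1, single-spectrum clusters
   are also fitted from the survey scan at the cluster apex (AS) and the
   survey scan immediately preceding the identification (PS), and the best
   of the three is kept. Single-spectrum clusters take the summed centroid
   intensity at each envelope position; positions with no centroid are
   missing.
6. The quantification value is the sum of theoretical intensities times the
   fitted intensity, and the H/L ratio is defined when both labels have a
   positive value.

**Prior-ion ratio.** The intensity at one neutron below the monoisotopic
peak (measured in the apex survey scan of the selected cluster) divided by
the summed fitted intensities. For a clean light peptide this position is
empty; an intense peak there means a co-eluting envelope overlaps the
cluster and the fitted intensity is unreliable. The filter threshold is
0.2.

## 3. From peptides to protein fold changes

PSMs condense into PCMs per run, keyed by sequence, charge and the
label-agnostic modification string, represented by the highest-scoring PSM
(ties: earliest scan). Peptide FDR is classical target-decoy counting at
descending score with q-value monotonisation. Protein groups are built from
peptides at ≤ 1% FDR; proteins with identical peptide sets share a group,
groups fully subsumed by a higher-scoring group are aggregated into it,
each reported group needs an anchor peptide (length ≥ 7, score margin ≥ 10
over the next-best different sequence for the same spectrum), and groups
sharing a gene identifier merge. The score margin is computed within each
spectrum's candidate list — the natural first-rank-vs-second-rank reading —
with the margin equal to the peptide's own score when the spectrum has no
competing sequence. Computing it within a whole run instead would allow at
most one anchor per run, which cannot be what an anchor rule intends.

Protein-level FDR uses the picked strategy: when a target and its decoy
(same accession, `DECOY_` prefix) are both identified, only the
higher-scoring member enters the decoy/target counting, avoiding decoy
inflation.

A protein's fold change at one time point is the **median H/L ratio of its
unique peptides** passing all five filters: score > 15, length ≥ 6,
q ≤ 0.01, envelope fit ≤ 0.1 for both labels, prior-ion ratio ≤ 0.2 for
both labels. A peptide whose label state was never measured has no fit or
prior value for that side; such missing values do not fail the filters —
the peptide simply contributes an undetermined ratio, and undetermined
ratios are excluded from the median whenever at least one surviving peptide
has a positive ratio.

## 4. Half-life estimation

In a non-dividing cell the light (pre-existing) pool of a protein decays
with first-order rate *k*, and the heavy pool accumulates correspondingly,
so the measured ratio follows *r(t) = e^kt^ − 1* and
*log(r + 1) = k·t* exactly. The estimator is the through-origin
least-squares slope:

$$k_{dp} = \frac{\sum_i \log(r_{t_i}+1)\,t_i}{\sum_i t_i^2},
\qquad T_{1/2} = \frac{\log 2}{k_{dp}}.$$

Undetermined fold changes are skipped; a *t* = 0 point contributes nothing
and is excluded. A non-positive rate means the protein did not measurably
degrade within the observation window; its half-life is reported as
undetermined rather than clipped to an arbitrary cap, so downstream
summaries see `NA`, not a fake bound.

Fit quality is the squared Pearson correlation between *t* and
*log(r + 1)*. A through-origin R² would be an alternative reading; the
Pearson form was chosen because it is the named statistic in common use for
this filter and is scale-free. The high-quality subset uses R² > 0.85, and
the structure colour maps relax this to R² ≥ 0.25 (a colour is useful at
lower confidence than a reported number).

QC labels, for the standard four-time-point design: `weak` if at least
three of four time points have a fold change; `good` if at least three are
each based on ≥ 3 quantified peptides; `poor` otherwise.

`merge_replicates()` reports the arithmetic-mean half-life (hour scale) for
proteins measured in at least two biological replicates — the hour-scale
mean is validated in the tests against printed replicate pairs
(2168.8/2315.5 → 2242 h; 945.9/995.9 → 971 h; 1479.9/1623.5 → 1552 h).

## 5. Complex-coherence statistics

Half-lives are mapped to annotated complexes (CORUM-style tables); a
complex is usable with ≥ 5 measured members. The observed statistic is the
per-complex SD of log10 half-lives. The chance reference reshuffles the
member proteins across the usable complexes, preserving every group size
and the half-life multiset (both asserted at each shuffle), and recomputes
the SDs; 1000 shuffles by default, fully seeded.

Two p-values are reported:

* **`p_value`** (primary): the exact permutation tail probability of the
  *median* within-complex SD, `(1 + #{shuffle medians ≤ observed}) /
  (n_shuffles + 1)`. Under a null in which membership carries no half-life
  information this is uniform by construction, which the test suite
  verifies by a 200-run type-I-error simulation. Its resolution is limited
  to 1/(n_shuffles + 1).
* **`rank_sum_p`** (secondary): a one-sided Wilcoxon rank-sum test of the
  observed SDs against the pooled shuffled SDs, the comparison usually
  displayed alongside such shuffle references. Because both samples are
  functions of the same pooled half-lives they are not independent, and
  this p-value is markedly conservative (in our null simulations it
  essentially never rejects); it is provided for presentation, not for
  calibrated inference.

`compare_annotated_groups()` contrasts two annotated subunit sets
(e.g. core vs regulatory particle subunits, scaffold vs peripheral
nucleoporins, or compartment annotations) by a rank-sum test on log10
half-lives — here the two groups are genuinely disjoint samples, so the
standard test applies, exact at small sizes. `pairwise_halflife_rmse()`
computes, for proteins measured in all compared cell types, the RMSE
between log10 half-life vectors (a metric), clustered with average linkage;
leaf order is deterministic. `halflife_color_map()` maps subunit half-lives
onto a red–white–blue gradient whose midpoint is the mean of per-replicate
medians and whose bounds are the means of the per-replicate 15th/85th
percentiles (linear-interpolation quantiles); values outside the bounds are
clipped, undetermined subunits are flagged green, and fused multi-subunit
segments take their members' mean.

## 6. What the synthetic data emulates — and what it does not

`simulate_ms1_map()` generates centroided survey scans in which each
peptide's light and heavy ladders elute as Gaussian peaks (default width
0.05 min, scan interval 1.2 s — a peak shape chosen for analytic half-height
checks, not for chromatographic realism), with per-centroid multiplicative
log-normal noise. Mixing ratios follow the evaluation design (1:1, 1:9,
1:49). Planted interference places an averagine-composition envelope of the
same charge one neutron below a chosen label's monoisotopic peak — the
exact situation the prior-ion ratio flags. Simulated peptide sets are drawn
collision-free (no two co-eluting peptides share any ladder position within
30 ppm), so that in un-planted scenarios the ground-truth ratio is the only
signal; real data contain such collisions, which is precisely why the
prior-ion filter exists.

`simulate_time_course()` inverts the decay model with multiplicative
log-normal noise on the ratio itself (keeping fold changes non-negative
regardless of how slow the turnover is). `simulate_complex_structure()`
draws complex centres and member scatter on the log10 scale;
`between_spread` is the *total* SD of the simulated log10 half-lives, so
setting `within_sd = between_spread` collapses all centres and yields an
exact null, while `within_sd` far below `between_spread` plants coherent
structure. `simulate_experiment()` wires everything together — per-run maps
whose pair ratios follow each protein's decay curve, PSM tables with
decoys, a design table — for end-to-end pipeline tests.

Passing tests on these simulations demonstrate the correctness of the
estimators and the internal consistency of the pipeline under the stated
noise model. They do **not** demonstrate robustness to phenomena the
generator omits: chromatographic tailing and retention drift, saturation
and detector nonlinearity, incomplete label incorporation (which produces
genuine low-level prior ions for heavy peptides), missed or chimeric
identifications, and run-to-run normalisation issues.

## 7. Numerical choices and limitations

* Default pulse design: 7, 11, 24, 34 h, four time points; problem sizes in
  the test and acceptance runs (tens of peptides per map, 500 proteins for
  recovery, 200 null simulations at ~200 shuffles, 1000 shuffles for the
  planted case) were chosen as the smallest sizes at which the statistical
  properties under test are stable.
* Ties in candidate selection: equal fit quality prefers the higher fitted
  intensity, then the earlier apex — deterministic ordering.
* Percentiles use R's default linear interpolation between order
  statistics (type 7).
* The m/z of isotope *i* is the monoisotopic m/z plus *i* neutron spacings;
  per-isotopologue centroid shifts are below 10 ppm relevance for tryptic
  peptides.
* All stochastic steps consume explicit seeds; two runs with identical seed
  and configuration produce byte-identical output tables
  (`write_results()` serialises doubles at 17 significant digits).
* The package does not read vendor raw files (mzML via `mzR`, or its own
  TSV spectrum tables, are the inputs), does not perform the database
  search, and computes — but does not render — structure colour values.
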