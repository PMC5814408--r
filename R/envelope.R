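# Theoretical isotopic envelopes.
#
# The envelope is computed on the neutron-count grid: every natural isotope
# contributes at an integer offset from the principal isotope, so the
# aggregated distribution of a molecule is the convolution of the per-atom
# offset distributions. Truncating the working vector to L entries during the
# convolution is exact for the first L entries because the distributions are
# non-negative and offsets only add.

# distribution^n by binary exponentiation, all vectors truncated to len.
.conv_pow <- function(dist, n, len) {
  result <- c(1, numeric(len - 1L))
  base <- dist[seq_len(min(length(dist), len))]
  length(base) <- len
  base[is.na(base)] <- 0
  while (n > 0) {
    if (n %% 2 == 1) result <- .conv_trunc(result, base, len)
    n <- n %/% 2
    if (n > 0) base <- .conv_trunc(base, base, len)
  }
  result
}

.conv_trunc <- function(a, b, len) {
  out <- numeric(len)
  for (i in seq_len(len)) {
    j <- seq_len(i)
    out[i] <- sum(a[j] * b[i - j + 1L])
  }
  out
}

# Aggregated isotopologue distribution over the first `len` neutron offsets.
.composition_distribution <- function(comp, len) {
  dist <- c(1, numeric(len - 1L))
  for (e in .elements) {
    n_free <- comp$counts[[e]]
    if (e %in% names(comp$fixed)) n_free <- n_free - comp$fixed[[e]]
    if (n_free <= 0) next
    iso <- .isotope_table[[e]]
    atom <- numeric(max(iso$offset) + 1L)
    atom[iso$offset + 1L] <- iso$abundance
    dist <- .conv_trunc(dist, .conv_pow(atom, n_free, len), len)
  }
  dist
}

new_isotope_envelope <- function(isotope, mz, intensity, charge) {
  out <- tibble(isotope = as.integer(isotope), mz = mz, intensity = intensity)
  attr(out, "charge") <- as.integer(charge)
  class(out) <- c("isotope_envelope", class(out))
  out
}

#' Exact theoretical isotopic envelope of a composition
#'
#' Convolves the natural-abundance isotope distributions of every free atom
#' in the composition; fixed heavy atoms (SILAC-substituted 13C/15N) are
#' point masses and only shift the monoisotopic mass. The envelope is
#' truncated to `n_isotopes` entries and renormalised to sum 1. Peak `i` is
#' placed at the monoisotopic m/z plus `i` times the 13C-12C mass difference
#' divided by the charge.
#'
#' @param comp A `peptide_composition`.
#' @param charge Positive integer charge state.
#' @param n_isotopes Number of isotope peaks to keep. Default (`NULL`): the
#'   smallest number whose un-truncated cumulative probability reaches 0.999,
#'   capped at 8. Exactly-zero trailing entries are dropped, so a composition
#'   whose atoms are all fixed collapses to a single point mass.
#' @return A tibble of class `isotope_envelope` with columns `isotope`
#'   (0-based index), `mz` (Th) and `intensity` (relative, sums to 1); the
#'   charge is carried as an attribute.
#' @examples
#' env <- exact_envelope(composition_of_peptide("PEPTIDEK"), charge = 2)
#' sum(env$intensity)
#' @export
exact_envelope <- function(comp, charge, n_isotopes = NULL) {
  stopifnot(inherits(comp, "peptide_composition"), charge >= 1)
  if (sum(comp$counts) == 0) abort("Empty composition: no atoms to build an envelope from.")
  if (!is.null(n_isotopes) && n_isotopes < 2) abort("n_isotopes must be at least 2.")
  work_len <- max(12L, n_isotopes %||% 0L)
  dist <- .composition_distribution(comp, work_len)
  if (is.null(n_isotopes)) {
    n_isotopes <- max(2L, min(8L, which(cumsum(dist) >= 0.999)[1]))
  }
  intensity <- dist[seq_len(n_isotopes)]
  intensity[is.na(intensity)] <- 0
  # drop exactly-zero tail entries (point-mass compositions)
  n_isotopes <- max(1L, max(which(intensity > 0)))
  intensity <- intensity[seq_len(n_isotopes)]
  intensity <- intensity / sum(intensity)
  mono_mz <- monoisotopic_mz(comp, charge)
  idx <- seq_len(n_isotopes) - 1L
  new_isotope_envelope(idx, mono_mz + idx * .neutron_mass / charge, intensity, charge)
}

#' Averagine approximation of an isotopic envelope
#'
#' Estimates a composition from the monoisotopic mass alone by scaling the
#' averagine average-amino-acid unit, rounding C/N/O/S counts and balancing
#' the mass remainder with hydrogens, then computes the envelope of that
#' estimated composition. Serves as a baseline for comparison with
#' [exact_envelope()]: it ignores how an individual peptide (for example a
#' cysteine-rich one) deviates from the proteome-average composition.
#'
#' @param monoisotopic_mass Target neutral monoisotopic mass (Da), > 0.
#' @param charge Positive integer charge state.
#' @param n_isotopes As in [exact_envelope()].
#' @return An `isotope_envelope` tibble.
#' @export
averagine_envelope <- function(monoisotopic_mass, charge, n_isotopes = NULL) {
  stopifnot(monoisotopic_mass > 0, charge >= 1)
  comp <- averagine_composition(monoisotopic_mass)
  env <- exact_envelope(comp, charge, n_isotopes)
  # report the requested mass on the m/z axis, not the rounded-count mass
  mono_mz <- (monoisotopic_mass + charge * .proton_mass) / charge
  env$mz <- mono_mz + env$isotope * .neutron_mass / charge
  env
}

#' Averagine composition estimate for a target mass
#'
#' @param monoisotopic_mass Target neutral monoisotopic mass (Da).
#' @return A `peptide_composition` with integer counts whose mass
#'   approximates the target after hydrogen balancing.
#' @export
averagine_composition <- function(monoisotopic_mass) {
  stopifnot(monoisotopic_mass > 0)
  unit_mass <- sum(vapply(.elements, function(e) {
    .averagine_unit[[e]] * .isotope_table[[e]]$mass[1]
  }, numeric(1)))
  scale <- monoisotopic_mass / unit_mass
  counts <- round(scale * .averagine_unit)
  counts[["H"]] <- 0
  mass_heavy_atoms <- sum(vapply(.elements, function(e) {
    counts[[e]] * .isotope_table[[e]]$mass[1]
  }, numeric(1)))
  counts[["H"]] <- max(0, round((monoisotopic_mass - mass_heavy_atoms) / .isotope_table$H$mass[1]))
  new_peptide_composition(counts)
}
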