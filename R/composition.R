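#' Elemental composition of a labelled peptide ion
#'
#' Computes the exact elemental composition (C, H, N, O, S atom counts) of a
#' peptide from its sequence, supported modifications, and SILAC label state.
#' For the heavy label, the substituted atoms of lysine (6 x 13C + 2 x 15N)
#' and arginine (6 x 13C + 4 x 15N) are recorded as fixed heavy atoms: they
#' carry the label mass shift and are excluded from the natural-abundance
#' convolution when the isotopic envelope is computed.
#'
#' @param sequence Amino-acid sequence (20-letter alphabet, upper case).
#' @param modifications Character vector of modification tokens, applied once
#'   per occurrence. Supported: `"Carbamidomethyl"`, `"Oxidation"`,
#'   `"Acetyl"`. The SILAC label is controlled by `label`, not listed here.
#' @param label `"light"` or `"heavy"`.
#' @return An object of class `peptide_composition`: a list with `counts`
#'   (named integer vector of atoms per element) and `fixed` (named integer
#'   vector, heavy-substituted C and N atoms).
#' @examples
#' composition_of_peptide("PEPTIDEK", label = "heavy")
#' @export
composition_of_peptide <- function(sequence, modifications = character(), label = "light") {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  label <- match.arg(label, c("light", "heavy"))
  residues <- strsplit(toupper(sequence), "")[[1]]
  unknown <- setdiff(residues, names(.residue_formulas))
  if (length(unknown) > 0) {
    abort(paste0("Unknown residue(s) in sequence: ", paste(unique(unknown), collapse = ", ")))
  }
  counts <- Reduce(`+`, .residue_formulas[residues]) + .water
  for (mod in modifications) {
    if (!mod %in% names(.modification_formulas)) {
      abort(paste0("Unknown modification: '", mod, "'. Supported: ",
                   paste(names(.modification_formulas), collapse = ", ")))
    }
    counts <- counts + .modification_formulas[[mod]]
  }
  fixed <- c(C = 0L, N = 0L)
  if (label == "heavy") {
    for (res in names(.silac_substitutions)) {
      n_res <- sum(residues == res)
      if (n_res > 0) fixed <- fixed + n_res * .silac_substitutions[[res]]
    }
  }
  new_peptide_composition(counts, fixed)
}

new_peptide_composition <- function(counts, fixed = c(C = 0L, N = 0L)) {
  counts <- counts[.elements]
  counts[is.na(counts)] <- 0
  names(counts) <- .elements
  if (any(counts < 0)) abort("Element counts must be non-negative.")
  if (fixed[["C"]] > counts[["C"]] || fixed[["N"]] > counts[["N"]]) {
    abort("Fixed heavy atom counts exceed the element counts.")
  }
  structure(
    list(counts = as.integer(round(counts)) |> setNames(.elements),
         fixed = c(C = as.integer(fixed[["C"]]), N = as.integer(fixed[["N"]]))),
    class = "peptide_composition"
  )
}

#' @export
print.peptide_composition <- function(x, ...) {
  shown <- x$counts[x$counts > 0]
  cat("<peptide_composition> ", paste0(names(shown), shown, collapse = " "), "\n", sep = "")
  if (any(x$fixed > 0)) {
    cat("  fixed heavy: 13C x ", x$fixed[["C"]], ", 15N x ", x$fixed[["N"]], "\n", sep = "")
  }
  invisible(x)
}

#' Monoisotopic mass of a composition
#'
#' Sum of principal-isotope masses over all atoms, plus the 13C/15N mass
#' shifts of any fixed heavy atoms.
#'
#' @param comp A `peptide_composition`.
#' @return Mass in Da.
#' @export
monoisotopic_mass <- function(comp) {
  stopifnot(inherits(comp, "peptide_composition"))
  base <- sum(vapply(.elements, function(e) comp$counts[[e]] * .isotope_table[[e]]$mass[1], numeric(1)))
  base + comp$fixed[["C"]] * .mass_13c_shift + comp$fixed[["N"]] * .mass_15n_shift
}

#' Mass-to-charge ratio of the monoisotopic ion
#'
#' @param comp A `peptide_composition`.
#' @param charge Positive integer charge state (protonation assumed).
#' @return m/z in Th.
#' @export
monoisotopic_mz <- function(comp, charge) {
  stopifnot(charge >= 1)
  (monoisotopic_mass(comp) + charge * .proton_mass) / charge
}

#' SILAC mass shift for a peptide sequence
#'
#' Heavy-minus-light monoisotopic mass difference implied by the K/R content
#' of the sequence (+8.014199 Da per K, +10.008269 Da per R).
#'
#' @param sequence Amino-acid sequence.
#' @return Mass shift in Da.
#' @export
silac_mass_shift <- function(sequence) {
  residues <- strsplit(toupper(sequence), "")[[1]]
  shift_k <- 6 * .mass_13c_shift + 2 * .mass_15n_shift
  shift_r <- 6 * .mass_13c_shift + 4 * .mass_15n_shift
  sum(residues == "K") * shift_k + sum(residues == "R") * shift_r
}
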