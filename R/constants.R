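# Physical constants and composition tables used across the package.

# Isotope masses (Da) and natural abundances, IUPAC/CIAAW 2013 representative
# values. Rows per element are ordered by increasing neutron count; the offset
# is the neutron-count difference to the lightest (principal) isotope.
.isotope_table <- list(
  C = list(mass = c(12.0, 13.0033548378),
           abundance = c(0.9893, 0.0107),
           offset = c(0L, 1L)),
  H = list(mass = c(1.0078250319, 2.0141017779),
           abundance = c(0.999885, 0.000115),
           offset = c(0L, 1L)),
  N = list(mass = c(14.0030740052, 15.0001088984),
           abundance = c(0.99636, 0.00364),
           offset = c(0L, 1L)),
  O = list(mass = c(15.9949146221, 16.9991315, 17.9991604),
           abundance = c(0.99757, 0.00038, 0.00205),
           offset = c(0L, 1L, 2L)),
  S = list(mass = c(31.97207069, 32.97145850, 33.96786683, 35.96708088),
           abundance = c(0.9499, 0.0075, 0.0425, 0.0001),
           offset = c(0L, 1L, 2L, 4L))
)

.elements <- names(.isotope_table)

# 13C - 12C mass difference: spacing of the isotope ladder (Th at z = 1).
.neutron_mass <- 13.0033548378 - 12.0
.proton_mass <- 1.00727646688

.mass_13c_shift <- 13.0033548378 - 12.0
.mass_15n_shift <- 15.0001088984 - 14.0030740052

# Amino-acid residue formulas (residue = amino acid minus water).
.residue_formulas <- list(
  G = c(C = 2, H = 3,  N = 1, O = 1, S = 0),
  A = c(C = 3, H = 5,  N = 1, O = 1, S = 0),
  S = c(C = 3, H = 5,  N = 1, O = 2, S = 0),
  P = c(C = 5, H = 7,  N = 1, O = 1, S = 0),
  V = c(C = 5, H = 9,  N = 1, O = 1, S = 0),
  T = c(C = 4, H = 7,  N = 1, O = 2, S = 0),
  C = c(C = 3, H = 5,  N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  I = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  N = c(C = 4, H = 6,  N = 2, O = 2, S = 0),
  D = c(C = 4, H = 5,  N = 1, O = 3, S = 0),
  Q = c(C = 5, H = 8,  N = 2, O = 2, S = 0),
  K = c(C = 6, H = 12, N = 2, O = 1, S = 0),
  E = c(C = 5, H = 7,  N = 1, O = 3, S = 0),
  M = c(C = 5, H = 9,  N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7,  N = 3, O = 1, S = 0),
  F = c(C = 9, H = 9,  N = 1, O = 1, S = 0),
  R = c(C = 6, H = 12, N = 4, O = 1, S = 0),
  Y = c(C = 9, H = 9,  N = 1, O = 2, S = 0),
  W = c(C = 11, H = 10, N = 2, O = 1, S = 0)
)

.water <- c(C = 0, H = 2, N = 0, O = 1, S = 0)

# Supported (non-label) modifications as composition deltas.
.modification_formulas <- list(
  Carbamidomethyl = c(C = 2, H = 3, N = 1, O = 1, S = 0),
  Oxidation       = c(C = 0, H = 0, N = 0, O = 1, S = 0),
  Acetyl          = c(C = 2, H = 2, N = 0, O = 1, S = 0)
)

# SILAC heavy label: substituted atoms per labelled residue.
# K: 6 x 13C + 2 x 15N (+8.014199 Da); R: 6 x 13C + 4 x 15N (+10.008269 Da).
.silac_substitutions <- list(
  K = c(C = 6L, N = 2L),
  R = c(C = 6L, N = 4L)
)

# Averagine unit (Senko et al. average amino-acid composition).
.averagine_unit <- c(C = 4.9384, H = 7.7583, N = 1.3577, O = 1.4773, S = 0.0417)
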