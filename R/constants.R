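# Physical constants and the monoisotopic residue mass table. Every mass in the
# package flows through these values; they are defined once here and nowhere else.

#' Mass constants
#'
#' Monoisotopic masses (in Daltons) used throughout the package: one water
#' molecule (added to the residue-mass sum to obtain a neutral peptide mass)
#' and one proton (used to convert between m/z and neutral mass, and to charge
#' fragment ions).
#'
#' @format Named numeric vector with elements `water` and `proton`.
#' @export
mass_constants <- c(water = 18.010565, proton = 1.007276)

#' Monoisotopic residue masses
#'
#' Named numeric vector of monoisotopic masses (Daltons) of the amino-acid
#' residues (i.e. the mass contributed by one residue inside a peptide chain;
#' a free peptide additionally carries one water). Covers the 20 canonical
#' amino acids plus selenocysteine (U). Ambiguity codes (B, J, O, X, Z) have
#' no defined mass: peptides spanning them are skipped during digestion.
#'
#' @format Named numeric vector, names are one-letter residue codes.
#' @export
residue_masses <- c(
  G = 57.02146372, A = 71.03711378, S = 87.03202840, P = 97.05276384,
  V = 99.06841390, T = 101.04768846, C = 103.00918448, L = 113.08406396,
  I = 113.08406396, N = 114.04292744, D = 115.02694302, Q = 128.05857750,
  K = 128.09496300, E = 129.04259308, M = 131.04048508, H = 137.05891186,
  F = 147.06841390, R = 156.10111102, Y = 163.06332852, W = 186.07931294,
  U = 150.953636
)

# Fast lookup path: residue mass by utf8 code point. NA for any byte that is
# not a defined residue, so cumulative scans can detect undefined residues.
.residue_mass_by_code <- local({
  v <- rep(NA_real_, 127L)
  v[utf8ToInt(paste(names(residue_masses), collapse = ""))] <- unname(residue_masses)
  v
})

# The 20 canonical amino acids (used as the default synthetic-sequence alphabet).
.canonical_aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
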