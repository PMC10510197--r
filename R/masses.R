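# Monoisotopic mass constants.  Residue masses are the standard values used
# across proteomics search engines; water and proton carry full precision so
# derived fragment m/z values are stable to well below typical ppm tolerances.

AA_MONO <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

MASS_WATER <- 18.0105646837
MASS_PROTON <- 1.00727646677

# Fixed carbamidomethylation of cysteine (iodoacetamide alkylation), the one
# fixed modification the engine applies; on by default everywhere.
MOD_CARBAMIDOMETHYL <- 57.021464

#' Per-residue monoisotopic masses of a peptide
#'
#' @param sequence Peptide sequence (standard 20-letter alphabet).
#' @param cys_cam Apply fixed carbamidomethylation (+57.021464 Da) to C.
#' @return Numeric vector, one mass per residue.
#' @export
residue_masses <- function(sequence, cys_cam = TRUE) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  m <- unname(AA_MONO[aa])
  if (anyNA(m)) {
    stop("sequence contains non-standard residues: ",
         paste(unique(aa[is.na(m)]), collapse = ","))
  }
  if (cys_cam) m[aa == "C"] <- m[aa == "C"] + MOD_CARBAMIDOMETHYL
  m
}

#' Neutral monoisotopic peptide mass
#'
#' Sum of residue masses plus one water.
#'
#' @inheritParams residue_masses
#' @return Mass in Da.
#' @export
peptide_mass <- function(sequence, cys_cam = TRUE) {
  sum(residue_masses(sequence, cys_cam)) + MASS_WATER
}
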