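# Amino-acid residue masses (Da). Monoisotopic values are the standard
# elemental-composition sums used throughout PMF software; average values are
# provided for instruments calibrated on average mass.

AA_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

AA_AVG <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

MASS_WATER_MONO <- 18.010565
MASS_WATER_AVG <- 18.01528
MASS_PROTON <- 1.007276

# Commonly used fixed modification deltas (Da, monoisotopic)
MOD_CARBAMIDOMETHYL_C <- c(C = 57.02146)

#' Monoisotopic MH+ mass of peptides
#'
#' Computes the singly-protonated (MH+) mass of one or more peptides as the
#' sum of residue masses plus one water and one proton, optionally adding
#' fixed per-residue modification deltas.
#'
#' @param sequence character vector of peptide sequences over the 20-letter
#'   amino-acid alphabet.
#' @param mods named numeric vector of fixed modification deltas in Da, named
#'   by the modified residue (e.g. `c(C = 57.02146)` for
#'   carbamidomethyl-cysteine), or `NULL` for none.
#' @param monoisotopic logical; use monoisotopic residue masses (default) or
#'   average masses.
#' @return numeric vector of MH+ masses in Da.
#' @examples
#' peptide_mass("PEPTIDE")
#' peptide_mass("C", mods = c(C = 57.02146))
#' @export
peptide_mass <- function(sequence, mods = NULL, monoisotopic = TRUE) {
  if (length(sequence) == 0L) return(numeric(0))
  sequence <- toupper(as.character(sequence))
  if (anyNA(sequence) || any(!nzchar(sequence))) {
    stop("peptide_mass: empty or missing sequence")
  }
  residue <- if (monoisotopic) AA_MONO else AA_AVG
  water <- if (monoisotopic) MASS_WATER_MONO else MASS_WATER_AVG
  if (!is.null(mods)) {
    if (is.null(names(mods)) || !all(names(mods) %in% names(residue))) {
      stop("peptide_mass: mods must be named by standard residues")
    }
    residue[names(mods)] <- residue[names(mods)] + mods
  }
  # one pass over the concatenated residues, then a grouped sum
  chars <- strsplit(paste(sequence, collapse = ""), "", fixed = TRUE)[[1L]]
  idx <- match(chars, names(residue))
  if (anyNA(idx)) {
    bad <- unique(chars[is.na(idx)])
    stop("peptide_mass: unknown residue(s): ", paste(bad, collapse = ", "))
  }
  grp <- rep.int(seq_along(sequence), nchar(sequence))
  res_sum <- as.numeric(rowsum(residue[idx], grp, reorder = TRUE))
  res_sum + water + MASS_PROTON
}
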