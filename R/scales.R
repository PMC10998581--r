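## Amino-acid alphabet and physicochemical scale tables.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

SUBSET_LEVELS <- c("TYPE1", "TYPE17", "IMMATURE", "INTERMEDIATE",
                   "CYCLING", "UNASSIGNED")
ANNOTATION_LEVELS <- c("TYPE1", "TYPE17", "TYPE1_TYPE17", "OTHER")

# Kyte-Doolittle hydropathy (positive = hydrophobic).
.KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

# Gas-phase basicity (kcal/mol), the per-residue basicity table used by
# repertoire-analysis toolkits; R/K/H carry the highest values.
.BASICITY <- c(
  A = 206.4, C = 206.2, D = 208.6, E = 215.6, F = 212.1, G = 202.7,
  H = 223.7, I = 210.8, K = 221.8, L = 209.6, M = 213.3, N = 212.8,
  P = 214.4, Q = 214.2, R = 237.0, S = 207.6, T = 211.7, V = 208.7,
  W = 216.1, Y = 213.1)

# Chou-Fasman alpha-helix propensity P(alpha).
.HELIX <- c(
  A = 1.42, C = 0.70, D = 1.01, E = 1.51, F = 1.13, G = 0.57, H = 1.00,
  I = 1.08, K = 1.16, L = 1.21, M = 1.45, N = 0.67, P = 0.57, Q = 1.11,
  R = 0.98, S = 0.77, T = 0.83, V = 1.06, W = 1.08, Y = 0.69)

#' Bundled amino-acid physicochemical scales
#'
#' Returns the named per-residue scales used by [physchem_profile()] and by
#' the simulator's default instructive commitment function: Kyte-Doolittle
#' hydropathy (`hydrophobicity`), gas-phase basicity in kcal/mol
#' (`basicity`) and Chou-Fasman alpha-helix propensity (`helix_propensity`).
#' Any user-supplied named vector over the 20 residues can be used instead.
#'
#' @return Named list of three numeric vectors, each named by the 20
#'   one-letter amino-acid codes.
#' @export
#' @examples
#' aa_scales()$hydrophobicity[["W"]]
aa_scales <- function() {
  list(hydrophobicity = .KYTE_DOOLITTLE,
       basicity = .BASICITY,
       helix_propensity = .HELIX)
}

## Translate in-frame nucleotide strings to amino acids (stop = "*").
translate_nt <- function(nt) {
  if (length(nt) == 0L) return(character(0))
  stopifnot(all(nchar(nt) %% 3L == 0L))
  out <- character(length(nt))
  nonempty <- nchar(nt) > 0L
  if (any(nonempty)) {
    aa <- Biostrings::translate(Biostrings::DNAStringSet(nt[nonempty]),
                                if.fuzzy.codon = "error")
    out[nonempty] <- as.character(aa)
  }
  out
}

## Mean value of a scale over the residues of each sequence.
mean_scale <- function(seqs, scale) {
  vapply(strsplit(seqs, ""), function(ch) mean(scale[ch]), numeric(1))
}
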