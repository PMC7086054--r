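#' Five physicochemical z-descriptors of the 20 standard amino acids
#'
#' The extended z-scale table of Sandberg et al. (1998, J Med Chem 41:2481):
#' five orthogonal scores per residue summarizing lipophilicity (z1),
#' steric bulk / polarizability (z2), polarity (z3) and electronic
#' effects (z4, z5), derived from 26 measured and computed physicochemical
#' properties. Substituting each amino acid by its z-vector turns a peptide
#' position into five real coordinates, the standard encoding for clustering
#' MHC alleles into functional supertypes by the biochemistry of their
#' antigen-binding residues.
#'
#' @format A 20 x 5 numeric matrix; rownames are one-letter amino-acid
#'   codes, columns `z1`..`z5`.
#' @export
Z_SCALES <- local({
  m <- matrix(c(
    # z1     z2     z3     z4     z5
     0.24, -2.32,  0.60, -0.14,  1.30,  # A
     3.52,  2.50, -3.50,  1.99, -0.17,  # R
     3.05,  1.62,  1.04, -1.15,  1.61,  # N
     3.98,  0.93,  1.93, -2.46,  0.75,  # D
     0.84, -1.67,  3.71,  0.18, -2.65,  # C
     1.75,  0.50, -1.44, -1.34,  0.66,  # Q
     3.11,  0.26, -0.11, -3.04, -0.25,  # E
     2.05, -4.06,  0.36, -0.82, -0.38,  # G
     2.47,  1.95,  0.26,  3.90,  0.09,  # H
    -3.89, -1.73, -1.71, -0.84,  0.26,  # I
    -4.28, -1.30, -1.49, -0.72,  0.84,  # L
     2.29,  0.89, -2.49,  1.49,  0.31,  # K
    -2.85, -0.22,  0.47,  1.94, -0.98,  # M
    -4.22,  1.94,  1.06,  0.54, -0.62,  # F
    -1.66,  0.27,  1.84,  0.70,  2.00,  # P
     2.39, -1.07,  1.15, -1.39,  0.67,  # S
     0.75, -2.18, -1.12, -1.46, -0.40,  # T
    -4.36,  3.94,  0.59,  3.44, -1.59,  # W
    -2.54,  2.44,  0.43,  0.04, -1.47,  # Y
    -2.59, -2.64, -1.54, -0.85, -0.02   # V
  ), ncol = 5, byrow = TRUE)
  rownames(m) <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  colnames(m) <- paste0("z", 1:5)
  m
})
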