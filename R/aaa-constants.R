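#' The twenty standard amino-acid one-letter codes
#'
#' Order is alphabetical by one-letter code. `X` (unknown residue) is accepted
#' by the readers and the scanner but is not part of this vector.
#'
#' @export
AA_ALPHABET20 <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

#' The ten class B flavoprotein monooxygenase groups
#'
#' YUCCA, YUC-like, cyanobacterial, type I/IIa/IIb/IIc FMOs, NMOs, BVMOs and
#' class G flavoprotein monooxygenases (the outgroup class).
#'
#' @export
FAMILY_LEVELS <- c(
  "YUCCA", "YUC_like", "cyanobacterial", "typeI", "typeIIa",
  "typeIIb", "typeIIc", "NMO", "BVMO", "classG"
)

#' The six FMO-like groups indistinguishable by FMO-motif consensus
#'
#' These share the FxGxxxHxxx[Y/F][K/R] FMO-motif consensus and can only be
#' separated with tree evidence.
#'
#' @export
FMO_LIKE_FAMILIES <- c(
  "YUCCA", "YUC_like", "cyanobacterial", "typeI", "typeIIa", "typeIIc"
)
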