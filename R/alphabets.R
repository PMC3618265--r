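#' The 20 standard amino acids, alphabetical one-letter order
#'
#' Fixed ordering used by [aac_vector()] and all descriptor column names.
#' @export
AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Three-group divisions of the 20 amino acids for the seven physicochemical
# properties used by the CTD descriptors (Dubchak-style groupings).  Group 1
# of hydrophobicity is polar, group 2 neutral, group 3 hydrophobic; this
# division reproduces the canonical encoding of MTEITAAMVKELRESTGAGA as
# 32132223311311222222.
.property_groups <- list(
  hydrophobicity = list(
    g1 = c("R", "K", "E", "D", "Q", "N"),
    g2 = c("G", "A", "S", "T", "P", "H", "Y"),
    g3 = c("C", "L", "V", "I", "M", "F", "W")
  ),
  normalized.vdw.volume = list(
    g1 = c("G", "A", "S", "T", "P", "D", "C"),
    g2 = c("N", "V", "E", "Q", "I", "L"),
    g3 = c("M", "H", "K", "F", "R", "Y", "W")
  ),
  polarity = list(
    g1 = c("L", "I", "F", "W", "C", "M", "V", "Y"),
    g2 = c("P", "A", "T", "G", "S"),
    g3 = c("H", "Q", "R", "K", "N", "E", "D")
  ),
  polarizability = list(
    g1 = c("G", "A", "S", "D", "T"),
    g2 = c("C", "P", "N", "V", "E", "Q", "I", "L"),
    g3 = c("K", "M", "H", "F", "R", "Y", "W")
  ),
  charge = list(
    g1 = c("K", "R"),
    g2 = c("A", "N", "C", "Q", "G", "H", "I", "L", "M", "F", "P", "S",
           "T", "W", "Y", "V"),
    g3 = c("D", "E")
  ),
  secondary.structure = list(
    g1 = c("E", "A", "L", "M", "Q", "K", "R", "H"),
    g2 = c("V", "I", "Y", "C", "W", "F", "T"),
    g3 = c("G", "N", "P", "S", "D")
  ),
  solvent.accessibility = list(
    g1 = c("A", "L", "F", "C", "G", "I", "V", "W"),
    g2 = c("R", "K", "Q", "E", "N", "D"),
    g3 = c("M", "S", "P", "T", "H", "Y")
  )
)

#' Physicochemical property alphabets for CTD descriptors
#'
#' Returns the seven fixed three-group property alphabets (hydrophobicity,
#' normalized van der Waals volume, polarity, polarizability, charge,
#' secondary structure, solvent accessibility), each a named integer vector
#' mapping every standard amino acid to its group index in 1..3.
#'
#' @return Named list of 7 named integer vectors (names = amino acids,
#'   values in 1:3), in the fixed property order.
#' @examples
#' ab <- property_alphabets()
#' ab$hydrophobicity[["M"]]  # 3: hydrophobic group
#' @export
property_alphabets <- function() {
  lapply(.property_groups, function(p) {
    m <- integer(0)
    for (g in 1:3) {
      v <- rep.int(g, length(p[[g]]))
      names(v) <- p[[g]]
      m <- c(m, v)
    }
    m[AMINO_ACIDS]
  })
}

#' Names of the seven CTD property alphabets, in fixed order
#' @return Character vector of length 7.
#' @export
property_names <- function() names(.property_groups)
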