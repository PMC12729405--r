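# Shared constants: alphabets, region names, species labels, residue masses.

#' Canonical amino-acid alphabet
#'
#' The 20 canonical one-letter residue codes in alphabetical order. This
#' ordering is also the deterministic tie-break used when two residues reach
#' the same count at an alignment column.
#'
#' @return Character vector of length 20.
#' @export
aminoAcidAlphabet <- function() AA_ALPHABET20

AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

GAP_CHAR <- "-"

#' Region names of a VHH domain
#'
#' The seven segments of a single-domain antibody variable domain in
#' N- to C-terminal order: four framework regions interleaved with the
#' three complementarity-determining regions.
#'
#' @return Character vector `c("FR1","CDR1","FR2","CDR2","FR3","CDR3","FR4")`.
#' @export
regionNames <- function() REGIONS7

REGIONS7 <- c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4")

#' Accepted species categories
#'
#' The four camelid species into which heterogeneous source labels are
#' harmonized. Records that cannot be assigned to one of these are labelled
#' `"AMBIGUOUS"` and never reach a curated dataset.
#'
#' @return Character vector of the four binomial species names.
#' @export
speciesLevels <- function() SPECIES4

SPECIES4 <- c("Lama glama", "Vicugna pacos",
              "Camelus dromedarius", "Camelus bactrianus")

AMBIGUOUS_SPECIES <- "AMBIGUOUS"

# Average (not monoisotopic) residue masses in Da; a peptide's mass is the
# sum of its residue masses plus one water (18.01528 Da).
RESIDUE_MASS_DA <- c(
  A = 71.0788,  C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
  G = 57.0519,  H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
  M = 131.1926, N = 114.1038, P = 97.1167,  Q = 128.1307, R = 156.1875,
  S = 87.0782,  T = 101.1051, V = 99.1326,  W = 186.2132, Y = 163.1760
)

WATER_MASS_DA <- 18.01528

# Canonical column order of a curated record table.
CANONICAL_COLUMNS <- c("record_id", "source_db", "species", "full_sequence",
                       REGIONS7, "antigen", "doi", "pdb_code", "affinity",
                       "flags", "scheme")
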