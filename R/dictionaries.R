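# Fixed atom-name dictionaries for the moieties surveyed: aromatic amino-acid
# side-chain rings, nucleobase rings, deoxyribose units. Atom names follow
# PDB v3 conventions (primes, DA/DC/DG/DT); legacy star names and one-letter
# nucleotide codes are normalized on input.

AROMATIC_AA <- c("PHE", "TYR", "TRP", "HIS")
NUCLEOTIDES <- c("DA", "DC", "DG", "DT")

# ring atoms in cyclic (perimeter) order -- used both for plane fitting and
# as the polygon for lateral-offset participation tests. For Trp the full
# 9-atom bicyclic system is treated as one ring; the perimeter omits the
# fused CD2-CE2 bond.
AA_RING <- list(
  PHE = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
  TYR = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
  HIS = c("CG", "ND1", "CE1", "NE2", "CD2"),
  TRP = c("CG", "CD1", "NE1", "CE2", "CZ2", "CH2", "CZ3", "CE3", "CD2")
)

# exocyclic heavy substituents counted as part of the moiety for screening
AA_EXOCYCLIC <- list(
  PHE = "CB", TYR = c("CB", "OH"), HIS = "CB", TRP = "CB"
)

BASE_RING <- list(
  DA = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  DG = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  DC = c("N1", "C2", "N3", "C4", "C5", "C6"),
  DT = c("N1", "C2", "N3", "C4", "C5", "C6")
)

BASE_EXOCYCLIC <- list(
  DA = "N6",
  DG = c("O6", "N2"),
  DC = c("O2", "N4"),
  DT = c("O2", "O4", "C7")
)

SUGAR_RING <- c("C1'", "C2'", "C3'", "C4'", "O4'")
SUGAR_EXOCYCLIC <- c("C5'", "O5'", "O3'")

# element from a PDB atom name for the residues we recognize
element_of <- function(atom_name) substr(gsub("[^A-Z]", "", atom_name), 1L, 1L)

normalize_resid <- function(resid) {
  r <- toupper(trimws(resid))
  map <- c(A = "DA", C = "DC", G = "DG", T = "DT",
           ADE = "DA", CYT = "DC", GUA = "DG", THY = "DT")
  ifelse(r %in% names(map), map[r], r)
}

normalize_elety <- function(elety) {
  e <- gsub("\\*", "'", trimws(elety))
  # legacy thymine methyl
  e[e %in% c("C5M", "C7M")] <- "C7"
  e
}

is_purine <- function(resid) resid %in% c("DA", "DG")

#' Moiety definitions
#'
#' The fixed atom-name dictionaries describing which residues carry an
#' aromatic ring, a nucleobase ring or a deoxyribose unit, and which atoms
#' constitute each.
#'
#' @return named list with components `aromatic_aa_ring`, `nucleobase_ring`
#'   and `deoxyribose`, each mapping residue names to their ring atom names
#'   (cyclic order) and exocyclic heavy atoms.
#' @export
moiety_definitions <- function() {
  list(
    aromatic_aa_ring = lapply(stats::setNames(AROMATIC_AA, AROMATIC_AA),
      function(r) list(ring = AA_RING[[r]], exocyclic = AA_EXOCYCLIC[[r]])),
    nucleobase_ring = lapply(stats::setNames(NUCLEOTIDES, NUCLEOTIDES),
      function(r) list(ring = BASE_RING[[r]], exocyclic = BASE_EXOCYCLIC[[r]])),
    deoxyribose = list(ring = SUGAR_RING, exocyclic = SUGAR_EXOCYCLIC)
  )
}
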