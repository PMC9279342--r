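# Element parameter tables. Radii are Bondi van der Waals radii (Angstrom);
# masses are IUPAC standard atomic weights (amu), rounded to 3 decimals.

.bondi_radii <- c(
  H = 1.20, D = 1.20, HE = 1.40,
  C = 1.70, N = 1.55, O = 1.52, F = 1.47, NE = 1.54,
  SI = 2.10, P = 1.80, S = 1.80, CL = 1.75, AR = 1.88,
  BR = 1.85, I = 1.98,
  "NA" = 2.27, K = 2.75, MG = 1.73, CA = 2.31, ZN = 1.39, CU = 1.40,
  NI = 1.63, FE = 2.00, MN = 2.00, LI = 1.82
)

.standard_masses <- c(
  H = 1.008, D = 2.014, HE = 4.003,
  C = 12.011, N = 14.007, O = 15.999, F = 18.998, NE = 20.180,
  SI = 28.085, P = 30.974, S = 32.06, CL = 35.45, AR = 39.948,
  BR = 79.904, I = 126.904,
  "NA" = 22.990, K = 39.098, MG = 24.305, CA = 40.078, ZN = 65.38,
  CU = 63.546, NI = 58.693, FE = 55.845, MN = 54.938, LI = 6.94
)

#' Default residue names recognized as water
#'
#' Covers the common file dialects for explicit-water models (TIP3P and
#' friends): `HOH`, `WAT`, `SOL`, `TIP3`.
#'
#' @return Character vector of 3/4-letter residue names.
#' @export
water_residue_names <- function() c("HOH", "WAT", "SOL", "TIP3")

#' Default hydrophobic residue classification set
#'
#' Standard hydrophobic amino acids including tyrosine:
#' ALA, VAL, LEU, ILE, MET, PHE, TRP, CYS, TYR.
#'
#' @return Character vector of 3-letter residue names.
#' @export
default_hydrophobic_set <- function() {
  c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP", "CYS", "TYR")
}

# One-letter codes used for residue labels such as "V520".
.aa_one_letter <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

# Element symbol from a PDB atom name when the element column is absent.
.element_from_name <- function(name) {
  vapply(name, function(nm) {
    nm <- gsub("[0-9']", "", trimws(nm))
    if (nchar(nm) == 0L) return("")
    two <- toupper(substr(nm, 1, 2))
    if (two %in% c("CL", "BR", "MG", "FE", "ZN", "NA", "MN", "NI", "CU")) {
      return(two)
    }
    toupper(substr(nm, 1, 1))
  }, character(1), USE.NAMES = FALSE)
}
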