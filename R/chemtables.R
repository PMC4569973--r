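# Internal lookup tables: amino acids, atomic masses, valences, exclusions.

# 20 standard amino acids, three-letter -> one-letter
AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
         GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
         LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
         SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

AA_TYPES <- unname(AA3)  # canonical order of the 20-dim composition vector

# monoisotopic-free standard atomic weights (IUPAC 2021, rounded)
ATOMIC_MASS <- c(H = 1.008, D = 2.014, B = 10.81, C = 12.011, N = 14.007,
                 O = 15.999, F = 18.998, NA_ = 22.990, MG = 24.305,
                 SI = 28.085, P = 30.974, S = 32.06, CL = 35.45,
                 K = 39.098, CA = 40.078, MN = 54.938, FE = 55.845,
                 CO = 58.933, NI = 58.693, CU = 63.546, ZN = 65.38,
                 SE = 78.971, BR = 79.904, I = 126.904)

# default valences used to infer implicit hydrogen counts on SDF graphs
STD_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3, B = 3, SI = 4,
                 F = 1, CL = 1, BR = 1, I = 1, H = 1, SE = 2)

#' Default ligand exclusion list
#'
#' Chemical-component codes treated as crystallization additives, solvents
#' or common ions rather than biologically meaningful ligands: water, MES,
#' DMSO, glycerol, 2-mercaptoethanol, simple mono- and polyatomic ions, and
#' frequent cryoprotectants. The list is a curated approximation and is
#' user-overridable in [identify_ligands()].
#'
#' @format Character vector of 3-letter (or shorter) component codes.
#' @export
default_ligand_exclusions <- c(
  "HOH", "DOD", "WAT",                      # water
  "MES", "DMS", "GOL", "BME", "EDO", "PEG", # solvents / cryoprotectants
  "PG4", "PGE", "MPD", "TRS", "EPE", "ACT",
  "ACY", "FMT", "CIT", "TAR", "MLI",
  "NA", "CL", "K", "MG", "CA", "ZN", "MN",  # common ions
  "FE", "FE2", "NI", "CU", "CO", "CD", "HG",
  "SO4", "PO4", "NO3", "CO3", "BR", "IOD", "F"
)

aa_mass <- function(element) {
  e <- toupper(element)
  e[e == "NA"] <- "NA_"
  m <- ATOMIC_MASS[e]
  m[is.na(m)] <- 0
  unname(m)
}

res3_to_type <- function(res3) {
  out <- AA3[toupper(res3)]
  out[is.na(out)] <- "OTHER"
  unname(out)
}

is_heavy_element <- function(element) {
  !(toupper(element) %in% c("H", "D", "T"))
}
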