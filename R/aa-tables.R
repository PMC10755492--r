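# Amino-acid lookup tables shared across the package.

#' Standard amino acids
#'
#' Three-letter codes of the 20 standard amino acids, in alphabetical order.
#' All frequency vectors and the co-occurrence matrix are indexed by this set.
#'
#' @return Character vector of length 20.
#' @export
standard_aa <- function() {
  c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
    "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
}

.AA_3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V")

.AA_1TO3 <- stats::setNames(names(.AA_3TO1), unname(.AA_3TO1))

# Modified residues with a standard parent. MSE (selenomethionine) is by far
# the most common in crystal structures; the rest are frequent PTMs.
.NONSTANDARD_MAP <- c(
  MSE = "MET", SEC = "CYS", PYL = "LYS", HYP = "PRO", SEP = "SER",
  TPO = "THR", PTR = "TYR", CSO = "CYS", CME = "CYS", CSD = "CYS",
  KCX = "LYS", MLY = "LYS", M3L = "LYS", LLP = "LYS", FME = "MET",
  PCA = "GLU", CGU = "GLU", AIB = "ALA", DAL = "ALA", SAR = "GLY")

# Physicochemical classes partitioning the 20 standard amino acids.
.AA_CLASSES <- list(
  nonpolar = c("ALA", "VAL", "PRO", "LEU", "ILE", "TRP", "PHE"),
  polar    = c("SER", "THR", "TYR", "ASN", "GLN"),
  positive = c("LYS", "HIS", "ARG"),
  negative = c("GLU", "ASP"),
  special  = c("GLY", "CYS", "MET"))

# Backbone atom names; everything else on a standard residue is side chain.
.MAIN_CHAIN_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Map a residue code to its standard parent
#'
#' Nonstandard residue codes with a standard parent (e.g. MSE for
#' selenomethionine) are mapped to that parent; standard codes pass through;
#' anything else returns `NA`.
#'
#' @param resid Character vector of 3-letter residue codes.
#' @return Character vector of standard 3-letter codes, `NA` where unmappable.
#' @export
map_residue_code <- function(resid) {
  resid <- toupper(resid)
  out <- ifelse(resid %in% standard_aa(), resid,
                unname(.NONSTANDARD_MAP[resid]))
  as.character(out)
}

#' Convert 3-letter to 1-letter amino-acid codes
#' @param aa3 Character vector of standard 3-letter codes.
#' @return Character vector of 1-letter codes (`NA` for unknown codes).
#' @export
aa_three_to_one <- function(aa3) {
  unname(.AA_3TO1[toupper(aa3)])
}

# Hydrogen/deuterium detection: trust the element field when present,
# else fall back to the PDB atom-name heuristic (leading H or D after
# stripping leading digits, e.g. "1HB2").
.is_hydrogen <- function(elety, elesy) {
  elesy <- toupper(trimws(ifelse(is.na(elesy), "", elesy)))
  byel <- elesy %in% c("H", "D")
  blank <- elesy == ""
  stripped <- sub("^[0-9]+", "", toupper(trimws(elety)))
  byname <- substr(stripped, 1, 1) %in% c("H", "D")
  ifelse(blank, byname, byel)
}

# Residue key helpers: identity everywhere is (chain, resno, insert).
.res_key <- function(chain, resno, insert) {
  if (length(chain) == 0) return(character(0))
  insert <- ifelse(is.na(insert) | insert == " ", "", insert)
  paste0(chain, ":", resno, insert)
}

.pos_key <- function(resno, insert) {
  if (length(resno) == 0) return(character(0))
  insert <- ifelse(is.na(insert) | insert == " ", "", insert)
  paste0(resno, insert)
}
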