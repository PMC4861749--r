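# Assignable-atom rosters, pseudoatom conventions and a hydropathy scale
# for the 20 standard amino acids.  Chemically equivalent proton groups
# (methyls, fast-flipping pairs) appear once under their DYANA Q-name.

.side_chain <- list(
  ALA = c("CB", "QB"),
  ARG = c("CB", "HB2", "HB3", "CG", "HG2", "HG3", "CD", "HD2", "HD3",
          "NE", "HE"),
  ASN = c("CB", "HB2", "HB3", "CG", "ND2", "HD21", "HD22"),
  ASP = c("CB", "HB2", "HB3", "CG"),
  CYS = c("CB", "HB2", "HB3"),
  GLN = c("CB", "HB2", "HB3", "CG", "HG2", "HG3", "CD", "NE2", "HE21",
          "HE22"),
  GLU = c("CB", "HB2", "HB3", "CG", "HG2", "HG3", "CD"),
  GLY = character(),
  HIS = c("CB", "HB2", "HB3", "CG", "CD2", "HD2", "CE1", "HE1", "ND1",
          "NE2"),
  ILE = c("CB", "HB", "CG1", "HG12", "HG13", "CG2", "QG2", "CD1", "QD1"),
  LEU = c("CB", "HB2", "HB3", "CG", "HG", "CD1", "QD1", "CD2", "QD2"),
  LYS = c("CB", "HB2", "HB3", "CG", "HG2", "HG3", "CD", "HD2", "HD3",
          "CE", "HE2", "HE3", "NZ", "QZ"),
  MET = c("CB", "HB2", "HB3", "CG", "HG2", "HG3", "CE", "QE"),
  PHE = c("CB", "HB2", "HB3", "CG", "CD1", "HD1", "CD2", "HD2", "CE1",
          "HE1", "CE2", "HE2", "CZ", "HZ"),
  PRO = c("CB", "HB2", "HB3", "CG", "HG2", "HG3", "CD", "HD2", "HD3"),
  SER = c("CB", "HB2", "HB3"),
  THR = c("CB", "HB", "CG2", "QG2"),
  TRP = c("CB", "HB2", "HB3", "CG", "CD1", "HD1", "NE1", "HE1", "CE3",
          "HE3", "CZ2", "HZ2", "CZ3", "HZ3", "CH2", "HH2"),
  TYR = c("CB", "HB2", "HB3", "CG", "CD1", "HD1", "CD2", "HD2", "CE1",
          "HE1", "CE2", "HE2", "CZ"),
  VAL = c("CB", "HB", "CG1", "QG1", "CG2", "QG2"))

# methyl pseudoatoms per residue type (three equivalent protons; also the
# Lys NH3 group which gets the same bound correction)
.methyl_q <- list(ALA = "QB", VAL = c("QG1", "QG2"),
                  LEU = c("QD1", "QD2"), ILE = c("QG2", "QD1"),
                  THR = "QG2", MET = "QE", LYS = "QZ")

# Kyte-Doolittle hydropathy
.kd_scale <- c(ALA = 1.8, ARG = -4.5, ASN = -3.5, ASP = -3.5, CYS = 2.5,
               GLN = -3.5, GLU = -3.5, GLY = -0.4, HIS = -3.2, ILE = 4.5,
               LEU = 3.8, LYS = -3.9, MET = 1.9, PHE = 2.8, PRO = -1.6,
               SER = -0.8, THR = -0.7, TRP = -0.9, TYR = -1.3, VAL = 4.2)

#' Expected assignable atoms of a residue type
#'
#' Backbone N/HN/CA/HA(+HA2,HA3 for Gly)/C plus the side-chain roster, with
#' equivalent proton groups collapsed to their DYANA pseudoatom (QB, QG2,
#' ...).  Proline has no amide proton.
#'
#' @param residue_type 3-letter code.
#' @return character vector of atom names.
#' @export
residue_roster <- function(residue_type) {
  rt <- toupper(residue_type)
  if (!rt %in% names(.side_chain)) stop("unknown residue type: ", rt)
  bb <- c("N", "HN", "CA", "HA", "C")
  if (rt == "GLY") bb <- c("N", "HN", "CA", "HA2", "HA3", "C")
  if (rt == "PRO") bb <- setdiff(bb, "HN")
  c(bb, .side_chain[[rt]])
}

#' Hydrophobicity percentage of a residue type
#'
#' Kyte-Doolittle hydropathy min-max normalized to 0-100 over the 20
#' standard residues (ARG = 0, ILE = 100).
#'
#' @param residue_type 3-letter code(s).
#' @return numeric percentage(s).
#' @export
hydrophobicity_percent <- function(residue_type) {
  v <- .kd_scale[toupper(residue_type)]
  unname((v - min(.kd_scale)) / (max(.kd_scale) - min(.kd_scale)) * 100)
}

# upper-bound pad for pseudoatoms: methyl (and NH3) +1.0 A, any other
# pseudo group +0.7 A, explicit atoms 0
pseudoatom_correction <- function(residue_type, atom_name) {
  a <- toupper(atom_name)
  if (!startsWith(a, "Q")) return(0)
  rt <- toupper(residue_type)
  if (!is.na(rt) && rt %in% names(.methyl_q) && a %in% .methyl_q[[rt]])
    return(1.0)
  if (startsWith(a, "QQ")) return(1.0)   # stereo pair of methyls
  0.7
}

#' Expand a DYANA pseudoatom to its member protons
#'
#' \code{QB} maps to the protons \code{HB*} present in the supplied atom
#' names (e.g. HB2/HB3, or HB1/HB2/HB3 for an alanine methyl);
#' \code{QQG}-style names cover both branches.  Non-pseudoatom names map to
#' themselves.
#'
#' @param atom_name atom or pseudoatom name.
#' @param available character vector of explicit atom names present in the
#'   residue (from a structure or shift table).
#' @return character vector of member atom names (possibly empty).
#' @export
expand_pseudoatom <- function(atom_name, available) {
  a <- toupper(atom_name)
  if (!startsWith(a, "Q")) return(intersect(a, toupper(available)))
  stem <- sub("^QQ?", "", a)
  pat <- if (startsWith(a, "QQ"))
    paste0("^H", stem, "[0-9][0-9]?$") else paste0("^H", stem, "[0-9]$")
  grep(pat, toupper(available), value = TRUE)
}

# heavy atom bonded to a proton, resolved against the atom names known for
# the residue; used to pair e.g. HB2 with CB, HE1(Trp) with NE1, HN with N
attached_heavy <- function(proton_name, available) {
  h <- toupper(proton_name)
  avail <- toupper(available)
  if (h %in% c("H", "HN")) return(if ("N" %in% avail) "N" else NA_character_)
  stem <- sub("^H", "", h)
  while (nchar(stem) > 0) {
    for (cand in paste0(c("C", "N"), stem))
      if (cand %in% avail) return(cand)
    stem <- substr(stem, 1, nchar(stem) - 1)
  }
  NA_character_
}
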