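#' Structure ensemble
#'
#' Multi-model atomic coordinates sharing one atom roster, as produced by
#' NMR structure calculation.
#'
#' @param atoms data.frame with columns \code{residue_index},
#'   \code{residue_type}, \code{atom_name}, \code{element}.
#' @param xyz numeric array \code{c(n_atoms, 3, n_models)} in Angstrom.
#' @return an object of class \code{nmr_ensemble} with fields
#'   \code{atoms}, \code{xyz}, \code{sequence} (residue types indexed by
#'   residue number) and \code{n_models}.
#' @export
nmr_ensemble <- function(atoms, xyz) {
  if (length(dim(xyz)) == 2) xyz <- array(xyz, dim = c(dim(xyz), 1))
  stopifnot(nrow(atoms) == dim(xyz)[1], dim(xyz)[2] == 3)
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  res <- unique(atoms[, c("residue_index", "residue_type")])
  seqv <- stats::setNames(res$residue_type, res$residue_index)
  structure(list(atoms = atoms, xyz = xyz, sequence = seqv,
                 n_models = dim(xyz)[3]),
            class = "nmr_ensemble")
}

#' @export
print.nmr_ensemble <- function(x, ...) {
  cat(sprintf("<nmr_ensemble> %d models, %d atoms, %d residues\n",
              x$n_models, nrow(x$atoms), length(x$sequence)))
  invisible(x)
}

# n_atoms x 3 coordinate matrix of one model
model_xyz <- function(ensemble, model = 1) {
  matrix(ensemble$xyz[, , model], ncol = 3)
}

# row index of one atom (0-length if absent); "H" and "HN" are synonyms
atom_row <- function(ensemble, residue_index, atom_name) {
  a <- toupper(atom_name)
  if (a == "H") a <- "HN"
  which(ensemble$atoms$residue_index == residue_index &
        ensemble$atoms$atom_name == a)
}

.element_of <- function(atom_name) {
  substr(sub("^[0-9]*", "", toupper(atom_name)), 1, 1)
}

#' Read a multi-model PDB file as an ensemble
#'
#' MODEL/ENDMDL-delimited or single-model PDB, single chain, hydrogens
#' retained.  Every model must share the same atom roster; the first
#' differing atom is reported otherwise.  Amide protons named \code{"H"}
#' are normalized to \code{"HN"}.
#'
#' @param path input path.
#' @return an \code{\link{nmr_ensemble}}.
#' @export
read_ensemble_pdb <- function(path) {
  lines <- readLines(path)
  is_atom <- startsWith(lines, "ATOM")
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) > 1) {
    rosters <- lapply(seq_along(model_starts), function(k) {
      from <- model_starts[k]
      to <- if (k < length(model_starts)) model_starts[k + 1] - 1
            else length(lines)
      blk <- lines[from:to]
      blk <- blk[startsWith(blk, "ATOM")]
      paste(trimws(substr(blk, 23, 26)), trimws(substr(blk, 13, 16)))
    })
    for (k in seq_along(rosters)[-1]) {
      a <- rosters[[1]]; b <- rosters[[k]]
      if (length(a) != length(b) || any(a != b)) {
        d <- if (length(a) != length(b)) min(length(a), length(b)) + 1
             else which(a != b)[1]
        stop("atom roster of model ", k, " differs from model 1 at atom ",
             d, ": '", if (d <= length(b)) b[d] else "<missing>", "'")
      }
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  nm <- toupper(trimws(at$elety))
  nm[nm == "H"] <- "HN"
  ele <- if (!is.null(at$elesy) && any(nzchar(trimws(at$elesy))))
    toupper(trimws(at$elesy)) else .element_of(nm)
  ele[!nzchar(ele)] <- .element_of(nm[!nzchar(ele)])
  atoms <- data.frame(residue_index = at$resno,
                      residue_type = toupper(at$resid),
                      atom_name = nm, element = ele,
                      stringsAsFactors = FALSE)
  nmod <- nrow(pdb$xyz)
  xyz <- array(NA_real_, dim = c(nrow(atoms), 3, nmod))
  for (m in seq_len(nmod))
    xyz[, , m] <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
  nmr_ensemble(atoms, xyz)
}

#' Write an ensemble as a multi-model PDB file
#'
#' @param ensemble an \code{\link{nmr_ensemble}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_ensemble_pdb <- function(ensemble, path) {
  con <- file(path, "w")
  on.exit(close(con))
  at <- ensemble$atoms
  name4 <- ifelse(nchar(at$atom_name) < 4,
                  sprintf(" %-3s", at$atom_name),
                  at$atom_name)
  for (m in seq_len(ensemble$n_models)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- model_xyz(ensemble, m)
    writeLines(sprintf(
      "ATOM  %5d %4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(at)), name4, at$residue_type, at$residue_index,
      xyz[, 1], xyz[, 2], xyz[, 3], at$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
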