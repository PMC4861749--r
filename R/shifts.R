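#' Chemical-shift table
#'
#' One row per assigned atom: residue index, residue type (3-letter code),
#' atom name, mean shift (ppm), standard deviation over observations (ppm)
#' and the number of observations behind the mean.
#'
#' @param residue_index integer vector.
#' @param residue_type character vector (3-letter codes, e.g. "ALA").
#' @param atom_name character vector (IUPAC-ish names, e.g. "HN", "CA").
#' @param shift mean chemical shift, ppm.
#' @param sd standard deviation of the shift, ppm (0 when single-observed).
#' @param n_obs observation count (default 1).
#' @return a data.frame of class \code{shift_table}.
#' @export
shift_table <- function(residue_index, residue_type, atom_name, shift,
                        sd = 0, n_obs = 1L) {
  df <- data.frame(residue_index = as.integer(residue_index),
                   residue_type = toupper(as.character(residue_type)),
                   atom_name = toupper(as.character(atom_name)),
                   shift = as.numeric(shift),
                   sd = as.numeric(rep_len(sd, length(shift))),
                   n_obs = as.integer(rep_len(n_obs, length(shift))),
                   stringsAsFactors = FALSE)
  if (any(df$sd < 0)) stop("sd must be >= 0")
  if (any(df$n_obs < 1)) stop("n_obs must be >= 1")
  key <- paste(df$residue_index, df$atom_name)
  if (anyDuplicated(key))
    stop("duplicate atom entry: ", key[duplicated(key)][1])
  class(df) <- c("shift_table", "data.frame")
  df
}

# shift of one atom (NA if unassigned)
lookup_shift <- function(shifts, residue_index, atom_name) {
  i <- which(shifts$residue_index == residue_index &
             shifts$atom_name == toupper(atom_name))
  if (length(i)) shifts$shift[i[1]] else NA_real_
}

#' Write chemical shifts as a minimal NMR-STAR v3 loop
#'
#' Emits a single \code{Atom_chem_shift} loop (entity 1, ambiguity code 1)
#' of the kind accepted for BMRB-style deposition and readable by any STAR
#' parser.
#'
#' @param shifts a \code{\link{shift_table}} (nonempty).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_shifts_nmrstar <- function(shifts, path) {
  if (!nrow(shifts)) stop("empty shift table")
  hdr <- c("data_nmrstructkit_shifts", "",
           "save_assigned_chemical_shifts",
           "   _Assigned_chem_shift_list.Sf_category  assigned_chemical_shifts",
           "   _Assigned_chem_shift_list.ID            1", "",
           "   loop_",
           "      _Atom_chem_shift.ID",
           "      _Atom_chem_shift.Entity_ID",
           "      _Atom_chem_shift.Comp_index_ID",
           "      _Atom_chem_shift.Comp_ID",
           "      _Atom_chem_shift.Atom_ID",
           "      _Atom_chem_shift.Atom_type",
           "      _Atom_chem_shift.Val",
           "      _Atom_chem_shift.Val_err",
           "      _Atom_chem_shift.Ambiguity_code", "")
  rows <- sprintf("      %d 1 %d %s %s %s %.4f %.4f 1",
                  seq_len(nrow(shifts)), shifts$residue_index,
                  shifts$residue_type, shifts$atom_name,
                  substr(shifts$atom_name, 1, 1), shifts$shift, shifts$sd)
  writeLines(c(hdr, rows, "", "   stop_", "", "save_"), path)
  invisible(path)
}

#' Read the chemical-shift loop of a minimal NMR-STAR v3 file
#'
#' Inverse of \code{\link{write_shifts_nmrstar}}; understands the single
#' \code{Atom_chem_shift} loop that function emits.
#'
#' @param path input path.
#' @return a \code{\link{shift_table}}.
#' @export
read_shifts_nmrstar <- function(path) {
  lines <- readLines(path)
  tags <- grep("^\\s*_Atom_chem_shift\\.", lines)
  if (!length(tags)) stop("no Atom_chem_shift loop in ", path)
  cols <- sub("^\\s*_Atom_chem_shift\\.", "", trimws(lines[tags]))
  body <- lines[(max(tags) + 1):length(lines)]
  stop_i <- grep("^\\s*stop_", body)[1]
  body <- trimws(body[seq_len(stop_i - 1)])
  body <- body[nzchar(body)]
  mat <- do.call(rbind, strsplit(body, "\\s+"))
  colnames(mat) <- cols
  shift_table(residue_index = as.integer(mat[, "Comp_index_ID"]),
              residue_type = mat[, "Comp_ID"],
              atom_name = mat[, "Atom_ID"],
              shift = as.numeric(mat[, "Val"]),
              sd = as.numeric(mat[, "Val_err"]),
              n_obs = 1L)
}
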