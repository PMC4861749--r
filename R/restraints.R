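#' Distance-constraint table
#'
#' Atom-pair distance bounds in Angstrom with provenance and weight class.
#'
#' @param res_i,res_j residue indices.
#' @param atom_i,atom_j atom (or DYANA pseudoatom) names.
#' @param upper upper bound, Angstrom.
#' @param lower lower bound, Angstrom (default 1.8).
#' @param res_type_i,res_type_j 3-letter residue types (optional).
#' @param weight_class \code{"normal"}, \code{"promoted"} or
#'   \code{"demoted"}.
#' @param source \code{"noe"}, \code{"hbond"} or \code{"manual"}.
#' @return a data.frame of class \code{constraint_table}.
#' @export
constraint_table <- function(res_i, atom_i, res_j, atom_j, upper,
                             lower = 1.8, res_type_i = NA, res_type_j = NA,
                             weight_class = "normal", source = "noe") {
  n <- length(upper)
  df <- data.frame(res_i = as.integer(res_i),
                   res_type_i = toupper(as.character(rep_len(res_type_i, n))),
                   atom_i = toupper(as.character(atom_i)),
                   res_j = as.integer(res_j),
                   res_type_j = toupper(as.character(rep_len(res_type_j, n))),
                   atom_j = toupper(as.character(atom_j)),
                   upper = as.numeric(upper),
                   lower = as.numeric(rep_len(lower, n)),
                   weight_class = as.character(rep_len(weight_class, n)),
                   source = as.character(rep_len(source, n)),
                   stringsAsFactors = FALSE)
  if (any(df$lower > df$upper)) stop("lower bound exceeds upper bound")
  same <- df$res_i == df$res_j & df$atom_i == df$atom_j
  if (any(same)) stop("constraint between an atom and itself")
  stopifnot(all(df$weight_class %in% c("normal", "promoted", "demoted")),
            all(df$source %in% c("noe", "hbond", "manual")))
  class(df) <- c("constraint_table", "data.frame")
  df
}

empty_constraints <- function() {
  constraint_table(integer(), character(), integer(), character(),
                   numeric())
}

#' Write distance constraints
#'
#' \code{dyana_upl}: one line per constraint,
#' \code{i RES atom_i  j RES atom_j  upper}.  \code{xplor}: NOE-style
#' \code{assign (resid i and name A)(resid j and name B) d dminus dplus}
#' with \code{(d, dminus, dplus) = (lower, 0, upper - lower)}, the common
#' convention for NOE tables and the one that round-trips both bounds.
#'
#' @param constraints a \code{\link{constraint_table}}.
#' @param path output path.
#' @param dialect \code{"dyana_upl"} or \code{"xplor"}.
#' @return \code{path}, invisibly.
#' @export
write_constraints <- function(constraints, path,
                              dialect = c("dyana_upl", "xplor")) {
  dialect <- match.arg(dialect)
  rt_i <- ifelse(is.na(constraints$res_type_i), "UNK",
                 constraints$res_type_i)
  rt_j <- ifelse(is.na(constraints$res_type_j), "UNK",
                 constraints$res_type_j)
  if (dialect == "dyana_upl") {
    lines <- sprintf("%4d %-4s %-5s %4d %-4s %-5s %8.2f",
                     constraints$res_i, rt_i, constraints$atom_i,
                     constraints$res_j, rt_j, constraints$atom_j,
                     constraints$upper)
  } else {
    lines <- sprintf(
      "assign (resid %d and name %s)(resid %d and name %s) %.2f %.2f %.2f",
      constraints$res_i, constraints$atom_i,
      constraints$res_j, constraints$atom_j,
      constraints$lower, 0, constraints$upper - constraints$lower)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read distance constraints
#'
#' Inverse of \code{\link{write_constraints}}.  DYANA upper-limit files
#' carry no lower bound; 1.8 Angstrom is assumed.
#'
#' @param path input path.
#' @param dialect \code{"dyana_upl"} or \code{"xplor"}.
#' @return a \code{\link{constraint_table}}.
#' @export
read_constraints <- function(path, dialect = c("dyana_upl", "xplor")) {
  dialect <- match.arg(dialect)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(empty_constraints())
  if (dialect == "dyana_upl") {
    f <- do.call(rbind, strsplit(lines, "\\s+"))
    if (ncol(f) < 7) stop("malformed .upl line: ", lines[1])
    return(constraint_table(res_i = as.integer(f[, 1]), atom_i = f[, 3],
                            res_j = as.integer(f[, 4]), atom_j = f[, 6],
                            upper = as.numeric(f[, 7]),
                            res_type_i = f[, 2], res_type_j = f[, 5]))
  }
  pat <- paste0("assign\\s*\\(resid\\s+(\\d+)\\s+and\\s+name\\s+(\\S+)\\s*\\)",
                "\\s*\\(resid\\s+(\\d+)\\s+and\\s+name\\s+(\\S+)\\s*\\)",
                "\\s+(\\S+)\\s+(\\S+)\\s+(\\S+)")
  m <- regmatches(lines, regexec(pat, lines))
  bad <- which(vapply(m, length, integer(1)) != 8)
  if (length(bad)) stop("malformed Xplor line ", bad[1], ": ", lines[bad[1]])
  f <- do.call(rbind, m)
  lower <- as.numeric(f[, 6])
  constraint_table(res_i = as.integer(f[, 2]), atom_i = f[, 3],
                   res_j = as.integer(f[, 4]), atom_j = f[, 5],
                   upper = lower + as.numeric(f[, 8]), lower = lower)
}
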