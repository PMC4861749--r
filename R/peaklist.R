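#' Create a peak
#'
#' @param position numeric ppm per dimension.
#' @param height signed intensity at the peak.
#' @param volume integrated intensity (optional).
#' @param assignment character vector of atom labels per dimension (e.g.
#'   \code{c("A5HN", "A5N")}), or \code{NA}.  Simulated peaks carry the
#'   \code{"_s"} suffix on each label.
#' @param flags character subset of \code{c("noise", "simulated")}.
#' @param root index of the root peak that seeded this pick (restricted
#'   picking), or \code{NA}.
#' @return an object of class \code{nmr_peak}.
#' @export
nmr_peak <- function(position, height = NA_real_, volume = NA_real_,
                     assignment = NULL, flags = character(), root = NA) {
  stopifnot(all(flags %in% c("noise", "simulated")))
  if (is.null(assignment)) assignment <- rep(NA_character_, length(position))
  if ("simulated" %in% flags)
    assignment <- ifelse(is.na(assignment) | grepl("_s$", assignment),
                         assignment, paste0(assignment, "_s"))
  structure(list(position = as.numeric(position),
                 height = as.numeric(height),
                 volume = as.numeric(volume),
                 assignment = as.character(assignment),
                 flags = flags, root = root),
            class = "nmr_peak")
}

#' Create a peak list
#'
#' @param peaks list of \code{\link{nmr_peak}} objects (all of the same
#'   dimensionality).
#' @param dimensionality number of dimensions; inferred from the first peak
#'   when omitted.
#' @param source_spectrum label of the originating spectrum.
#' @return an object of class \code{nmr_peaklist}.
#' @export
nmr_peaklist <- function(peaks = list(), dimensionality = NULL,
                         source_spectrum = "") {
  if (is.null(dimensionality)) {
    dimensionality <- if (length(peaks)) length(peaks[[1]]$position) else 2L
  }
  for (p in peaks)
    if (length(p$position) != dimensionality)
      stop("peak dimensionality mismatch")
  structure(list(dimensionality = as.integer(dimensionality),
                 peaks = peaks, source_spectrum = source_spectrum),
            class = "nmr_peaklist")
}

#' @export
length.nmr_peaklist <- function(x) length(x$peaks)

#' @export
print.nmr_peaklist <- function(x, ...) {
  cat(sprintf("<nmr_peaklist> %d peaks, %dD (%s)\n", length(x$peaks),
              x$dimensionality, x$source_spectrum))
  invisible(x)
}

#' Tabulate a peak list
#'
#' @param x an \code{nmr_peaklist}.
#' @param ... unused.
#' @return a data.frame with one row per peak: positions \code{w1..wN},
#'   assignment (joined with \code{"-"}), height, volume and flags.
#' @export
as.data.frame.nmr_peaklist <- function(x, ...) {
  n <- length(x$peaks)
  d <- x$dimensionality
  pos <- matrix(NA_real_, n, d,
                dimnames = list(NULL, paste0("w", seq_len(d))))
  out <- data.frame(assignment = character(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    p <- x$peaks[[i]]
    pos[i, ] <- p$position
    out$assignment[i] <- if (all(is.na(p$assignment))) "?-?" else
      paste(ifelse(is.na(p$assignment), "?", p$assignment), collapse = "-")
  }
  out <- cbind(out, as.data.frame(pos))
  out$height <- vapply(x$peaks, function(p) p$height, numeric(1))
  out$volume <- vapply(x$peaks, function(p) p$volume, numeric(1))
  out$flags <- vapply(x$peaks, function(p)
    paste(p$flags, collapse = ","), character(1))
  out
}

# parse one Sparky assignment tag like "A5HN-A5N" or "A5HN-N" into a
# data.frame(res_type, res_index, atom, simulated); "?" entries give NA
parse_assignment_tag <- function(tag, ndim) {
  toks <- strsplit(tag, "-", fixed = TRUE)[[1]]
  if (length(toks) != ndim)
    stop("assignment '", tag, "' does not have ", ndim, " fields")
  res_t <- rep(NA_character_, ndim); res_i <- rep(NA_integer_, ndim)
  atom <- rep(NA_character_, ndim); sim <- rep(FALSE, ndim)
  prev_t <- NA_character_; prev_i <- NA_integer_
  for (d in seq_along(toks)) {
    tk <- toks[d]
    if (grepl("_s$", tk)) { sim[d] <- TRUE; tk <- sub("_s$", "", tk) }
    if (tk == "?" || tk == "") next
    m <- regmatches(tk, regexec("^([A-Za-z])([0-9]+)(.+)$", tk))[[1]]
    if (length(m) == 4) {
      prev_t <- toupper(m[2]); prev_i <- as.integer(m[3]); atom[d] <- m[4]
    } else {
      atom[d] <- tk                       # residue carried from previous dim
    }
    res_t[d] <- prev_t; res_i[d] <- prev_i
  }
  data.frame(res_type = res_t, res_index = res_i, atom = atom,
             simulated = sim, stringsAsFactors = FALSE)
}

#' Read a peak list
#'
#' Supported dialects: \code{"sparky_list"} (the Sparky text export:
#' \code{Assignment w1 w2 [w3] [Data Height]}, with \code{?-?} marking
#' unassigned peaks) and \code{"tsv"} (the columns produced by
#' \code{\link{as.data.frame.nmr_peaklist}}).
#'
#' @param path input path.
#' @param dialect \code{"sparky_list"} or \code{"tsv"}.
#' @return an \code{\link{nmr_peaklist}}.
#' @export
read_peaklist <- function(path, dialect = c("sparky_list", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    df$flags <- if (is.null(df$flags)) "" else {
      f <- as.character(df$flags); f[is.na(f)] <- ""; f
    }
    wcols <- grep("^w[0-9]+$", names(df), value = TRUE)
    peaks <- lapply(seq_len(nrow(df)), function(i) {
      flg <- if (nzchar(df$flags[i])) strsplit(df$flags[i], ",")[[1]]
             else character()
      asg <- if (df$assignment[i] == "?-?") NULL
             else sub("_s$", "", strsplit(df$assignment[i], "-")[[1]])
      nmr_peak(as.numeric(df[i, wcols]), df$height[i], df$volume[i],
               assignment = asg, flags = flg)
    })
    return(nmr_peaklist(peaks, length(wcols)))
  }
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  lines <- lines[!grepl("^Assignment", lines)]
  if (!length(lines)) return(nmr_peaklist())
  ndim <- NULL
  peaks <- vector("list", length(lines))
  for (li in seq_along(lines)) {
    f <- strsplit(lines[li], "[ \t]+")[[1]]
    tag <- f[1]
    d_here <- length(strsplit(tag, "-", fixed = TRUE)[[1]])
    nnum <- length(f) - 1L
    if (nnum < d_here || nnum > d_here + 2L)
      stop("line ", li, ": expected ", d_here, " position columns (+ up to ",
           "height and volume), got ", nnum)
    if (is.null(ndim)) ndim <- d_here
    if (d_here != ndim)
      stop("line ", li, ": dimensionality changes from ", ndim,
           " to ", d_here)
    pos <- as.numeric(f[2:(1 + ndim)])
    hgt <- if (nnum >= ndim + 1L) as.numeric(f[ndim + 2L]) else NA_real_
    vol <- if (nnum >= ndim + 2L) as.numeric(f[ndim + 3L]) else NA_real_
    if (tag == paste(rep("?", ndim), collapse = "-")) {
      peaks[[li]] <- nmr_peak(pos, hgt, vol)
    } else {
      info <- parse_assignment_tag(tag, ndim)
      lbl <- ifelse(is.na(info$atom), NA_character_,
                    paste0(ifelse(is.na(info$res_type), "", info$res_type),
                           ifelse(is.na(info$res_index), "",
                                  info$res_index), info$atom))
      flg <- if (any(info$simulated)) "simulated" else character()
      peaks[[li]] <- nmr_peak(pos, hgt, vol, assignment = lbl, flags = flg)
    }
  }
  nmr_peaklist(peaks, ndim)
}

#' Write a peak list
#'
#' @param peaklist an \code{\link{nmr_peaklist}}.
#' @param path output path.
#' @param dialect \code{"sparky_list"} or \code{"tsv"}.
#' @return \code{path}, invisibly.
#' @export
write_peaklist <- function(peaklist, path,
                           dialect = c("sparky_list", "tsv")) {
  dialect <- match.arg(dialect)
  df <- as.data.frame(peaklist)
  if (dialect == "tsv") {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  d <- peaklist$dimensionality
  lines <- character(nrow(df) + 1)
  lines[1] <- paste(c("Assignment", paste0("w", seq_len(d)),
                      "Data Height"), collapse = "\t")
  for (i in seq_len(nrow(df))) {
    p <- peaklist$peaks[[i]]
    tag <- if (all(is.na(p$assignment))) paste(rep("?", d), collapse = "-")
           else paste(ifelse(is.na(p$assignment), "?", p$assignment),
                      collapse = "-")
    lines[i + 1] <- paste(c(tag, sprintf("%.4f", p$position),
                            format(p$height, digits = 8)),
                          collapse = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}
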