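#' Inter-proton contact map
#'
#' For every residue pair, the minimum distance between any of their
#' protons over all models, and a contact flag where that minimum falls
#' below the cutoff (default 5.5 Angstrom, the distance out to which
#' NOESY cross peaks are expected).  Symmetric; the diagonal is excluded.
#'
#' @param ensemble an \code{\link{nmr_ensemble}} containing hydrogens.
#' @param d_contact contact cutoff in Angstrom.
#' @return an object of class \code{contact_map}: \code{distance} and
#'   \code{contact} matrices (residue x residue, diagonal NA),
#'   \code{residues}, \code{d_contact}.
#' @export
contact_map <- function(ensemble, d_contact = 5.5) {
  hs <- which(ensemble$atoms$element == "H")
  if (!length(hs)) stop("ensemble has no hydrogens; contact map needs protons")
  res <- as.integer(names(ensemble$sequence))
  n <- length(res)
  dmin <- matrix(Inf, n, n, dimnames = list(res, res))
  hres <- match(ensemble$atoms$residue_index[hs], res)
  for (m in seq_len(ensemble$n_models)) {
    xyz <- model_xyz(ensemble, m)[hs, , drop = FALSE]
    dd <- as.matrix(stats::dist(xyz))
    for (a in seq_len(n)) {
      ia <- which(hres == a)
      if (!length(ia)) next
      for (b in seq_len(n)) {
        if (b <= a) next
        ib <- which(hres == b)
        if (!length(ib)) next
        v <- min(dd[ia, ib])
        if (v < dmin[a, b]) dmin[a, b] <- dmin[b, a] <- v
      }
    }
  }
  diag(dmin) <- NA
  contact <- dmin < d_contact
  structure(list(distance = dmin, contact = contact, residues = res,
                 d_contact = d_contact),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %d residues, %d contacts < %.2f A\n",
              length(x$residues),
              sum(x$contact[upper.tri(x$contact)], na.rm = TRUE),
              x$d_contact))
  invisible(x)
}

#' Per-residue NOE constraint counts by sequence range
#'
#' Constraints are classed by residue separation |i - j|: short (<= 1),
#' medium (2-4), long (>= 5), and counted once per involved residue
#' (so column sums add to twice the constraint count).
#'
#' @param constraints a \code{\link{constraint_table}}.
#' @param sequence character vector of residue types named by residue
#'   index.
#' @return data.frame \code{(residue_index, short, medium, long)}.
#' @export
noe_bar_chart <- function(constraints, sequence) {
  res <- as.integer(names(sequence))
  cnt <- matrix(0L, length(res), 3,
                dimnames = list(res, c("short", "medium", "long")))
  for (r in seq_len(nrow(constraints))) {
    sep <- abs(constraints$res_i[r] - constraints$res_j[r])
    cls <- if (sep <= 1) "short" else if (sep <= 4) "medium" else "long"
    for (ri in c(constraints$res_i[r], constraints$res_j[r])) {
      k <- match(ri, res)
      if (!is.na(k)) cnt[k, cls] <- cnt[k, cls] + 1L
    }
  }
  data.frame(residue_index = res, short = cnt[, "short"],
             medium = cnt[, "medium"], long = cnt[, "long"],
             row.names = NULL)
}
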