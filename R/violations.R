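# effective distance between two (pseudo)atom proton sets; "r6" applies
# r^-6 averaging over all member-pair distances, "center" measures
# between the mean member positions
.effective_distance <- function(xyz, rows_i, rows_j,
                                method = c("r6", "center")) {
  method <- match.arg(method)
  if (method == "center") {
    ci <- colMeans(xyz[rows_i, , drop = FALSE])
    cj <- colMeans(xyz[rows_j, , drop = FALSE])
    return(sqrt(sum((ci - cj)^2)))
  }
  d <- as.vector(outer(rows_i, rows_j, Vectorize(function(a, b)
    sqrt(sum((xyz[a, ] - xyz[b, ])^2)))))
  mean(d^-6)^(-1 / 6)
}

# ensemble atom rows matched by an atom or pseudoatom name
.constraint_rows <- function(ensemble, residue, atom) {
  rows <- atom_row(ensemble, residue, atom)
  if (length(rows)) return(rows)
  avail <- ensemble$atoms$atom_name[ensemble$atoms$residue_index == residue]
  members <- expand_pseudoatom(atom, avail)
  unlist(lapply(members, function(a) atom_row(ensemble, residue, a)))
}

#' Check distance constraints against a structure ensemble
#'
#' Per constraint and model, the inter-atom distance (pseudoatoms are
#' r^-6-averaged over their member protons) and the violations
#' \code{max(0, d - upper)} and \code{max(0, lower - d)}.  A constraint
#' is flagged when its mean upper violation exceeds \code{threshold} or
#' its worst model exceeds \code{max_single}.
#'
#' @param ensemble an \code{\link{nmr_ensemble}}.
#' @param constraints a \code{\link{constraint_table}}.
#' @param threshold mean-violation flag level, Angstrom (default 0.1).
#' @param max_single single-model flag level, Angstrom (default 0.5).
#' @param pseudo_method \code{"r6"} or \code{"center"}.
#' @return data.frame of class \code{violation_report}: one row per
#'   constraint with mean/min/max distance, mean and max violations and
#'   the flag; attribute \code{"flagged"} gives the flagged subset.
#' @export
violation_report <- function(ensemble, constraints, threshold = 0.1,
                             max_single = 0.5,
                             pseudo_method = c("r6", "center")) {
  pseudo_method <- match.arg(pseudo_method)
  n <- nrow(constraints)
  out <- cbind(constraints,
               data.frame(mean_dist = NA_real_, min_dist = NA_real_,
                          max_dist = NA_real_, mean_viol = NA_real_,
                          max_viol = NA_real_, flagged = FALSE))
  for (r in seq_len(n)) {
    ri <- .constraint_rows(ensemble, constraints$res_i[r],
                           constraints$atom_i[r])
    rj <- .constraint_rows(ensemble, constraints$res_j[r],
                           constraints$atom_j[r])
    if (!length(ri) || !length(rj)) {
      warning("constraint ", r, ": atom not found in ensemble, skipped")
      next
    }
    d <- vapply(seq_len(ensemble$n_models), function(m)
      .effective_distance(model_xyz(ensemble, m), ri, rj, pseudo_method),
      numeric(1))
    vu <- pmax(0, d - constraints$upper[r])
    vl <- pmax(0, constraints$lower[r] - d)
    v <- vu + vl
    out$mean_dist[r] <- mean(d)
    out$min_dist[r] <- min(d)
    out$max_dist[r] <- max(d)
    out$mean_viol[r] <- mean(v)
    out$max_viol[r] <- max(v)
    out$flagged[r] <- mean(v) > threshold || max(v) > max_single
  }
  class(out) <- c("violation_report", "data.frame")
  attr(out, "flagged") <- out[which(out$flagged), , drop = FALSE]
  out
}
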