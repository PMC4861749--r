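#' Enumerate candidate atom-pair assignments for NOESY peaks
#'
#' For each cross peak, every proton pair in the shift table matching the
#' peak position within tolerance is a candidate; for 3D NOESY the heavy
#' atom bonded to the second proton must also match the heavy dimension.
#' Demoted (blacklisted) residue pairs are removed.  If more than one
#' candidate remains and exactly one is promoted (whitelisted), it is
#' selected; otherwise the peak is marked ambiguous with all candidates
#' listed.
#'
#' @param peaklist a 2D or 3D NOESY \code{\link{nmr_peaklist}}.
#' @param shifts a nonempty \code{\link{shift_table}}.
#' @param tolerances ppm tolerance per nucleus class.
#' @param weights an optional \code{\link{pair_weights}}.
#' @param proton_dims the two proton dimensions (defaults:
#'   \code{c(1, 2)} for 2D, \code{c(1, 3)} for 3D).
#' @param heavy_dim the heavy-atom dimension of a 3D NOESY (default 2);
#'   the heavy atom is the one bonded to the proton of
#'   \code{proton_dims[2]}.
#' @return an object of class \code{noe_assignments}: a list with one
#'   record per peak (\code{peak}, \code{height}, \code{candidates}
#'   data.frame, \code{selected} row index or NA, \code{ambiguous}).
#' @export
assign_noe_candidates <- function(peaklist, shifts,
                                  tolerances = c(H = 0.02, N = 0.2,
                                                 C = 0.2),
                                  weights = NULL, proton_dims = NULL,
                                  heavy_dim = NULL) {
  if (!nrow(shifts)) stop("empty shift table")
  nd <- peaklist$dimensionality
  if (!nd %in% c(2, 3)) stop("NOESY dimensionality must be 2 or 3")
  if (is.null(proton_dims)) proton_dims <- if (nd == 2) c(1, 2) else c(1, 3)
  if (nd == 3 && is.null(heavy_dim))
    heavy_dim <- setdiff(1:3, proton_dims)
  protons <- shifts[startsWith(shifts$atom_name, "H") |
                    startsWith(shifts$atom_name, "Q"), , drop = FALSE]
  tolH <- unname(tolerances["H"])
  records <- lapply(seq_along(peaklist$peaks), function(pi) {
    p <- peaklist$peaks[[pi]]
    ia <- which(abs(protons$shift - p$position[proton_dims[1]]) <= tolH)
    ib <- which(abs(protons$shift - p$position[proton_dims[2]]) <= tolH)
    cand <- expand.grid(a = ia, b = ib)
    # a proton cannot cross-relax with itself
    cand <- cand[!(protons$residue_index[cand$a] ==
                   protons$residue_index[cand$b] &
                   protons$atom_name[cand$a] == protons$atom_name[cand$b]),
                 , drop = FALSE]
    if (nd == 3 && nrow(cand)) {
      keep <- vapply(seq_len(nrow(cand)), function(r) {
        b <- cand$b[r]
        ri <- protons$residue_index[b]
        avail <- shifts$atom_name[shifts$residue_index == ri]
        hv <- attached_heavy(protons$atom_name[b], avail)
        if (is.na(hv)) return(FALSE)
        tol <- unname(tolerances[nucleus_class(substr(hv, 1, 1))])
        if (is.na(tol)) tol <- unname(tolerances["C"])
        abs(lookup_shift(shifts, ri, hv) - p$position[heavy_dim]) <= tol
      }, logical(1))
      cand <- cand[keep, , drop = FALSE]
    }
    cdf <- data.frame(res_i = protons$residue_index[cand$a],
                      res_type_i = protons$residue_type[cand$a],
                      atom_i = protons$atom_name[cand$a],
                      res_j = protons$residue_index[cand$b],
                      res_type_j = protons$residue_type[cand$b],
                      atom_j = protons$atom_name[cand$b],
                      stringsAsFactors = FALSE)
    cdf$weight <- "normal"
    if (!is.null(weights) && nrow(cdf)) {
      cdf$weight <- vapply(seq_len(nrow(cdf)), function(r)
        pair_weight(weights, cdf$res_i[r], cdf$res_j[r]), character(1))
      cdf <- cdf[cdf$weight != "demoted", , drop = FALSE]
    }
    selected <- NA_integer_
    if (nrow(cdf) == 1) {
      selected <- 1L
    } else if (nrow(cdf) > 1 && sum(cdf$weight == "promoted") == 1) {
      selected <- which(cdf$weight == "promoted")
    }
    list(peak = pi, height = p$height, volume = p$volume,
         candidates = cdf, selected = selected,
         ambiguous = is.na(selected))
  })
  structure(records, class = "noe_assignments")
}

# records with a usable candidate, as one data.frame plus intensities
.selected_pairs <- function(assignments, observable = "height") {
  rows <- list()
  for (rec in assignments) {
    if (is.na(rec$selected)) next
    r <- rec$candidates[rec$selected, , drop = FALSE]
    r$intensity <- abs(if (observable == "volume") rec$volume
                       else rec$height)
    rows[[length(rows) + 1]] <- r
  }
  do.call(rbind, rows)
}

#' Generate distance constraints from assigned NOESY peaks
#'
#' Continuous mode converts each unambiguous peak's intensity to a
#' distance through the calibration and pads it: \code{upper = d(I) +
#' pad}, \code{lower = 1.8}.  Pseudoatom bound corrections are added to
#' the upper limit (+1.0 Angstrom per methyl group, +0.7 per other
#' pseudoatom).  Binned mode delegates to \code{\link{bin_constraints}}.
#'
#' @param assignments a \code{\link{assign_noe_candidates}} result.
#' @param calibration a \code{\link{noe_calibration}}.
#' @param mode \code{"continuous"} or \code{"binned"}.
#' @param pad upper-bound pad in Angstrom (default 0.5).
#' @param lower lower bound in Angstrom (default 1.8).
#' @return a \code{\link{constraint_table}}.
#' @export
generate_distance_constraints <- function(assignments, calibration,
                                          mode = c("continuous", "binned"),
                                          pad = 0.5, lower = 1.8) {
  mode <- match.arg(mode)
  if (!inherits(calibration, "noe_calibration"))
    stop("uncalibrated input: pass a noe_calibration")
  if (mode == "binned") return(bin_constraints(assignments))
  sel <- .selected_pairs(assignments)
  if (is.null(sel)) return(empty_constraints())
  d <- noe_distance(calibration, sel$intensity)
  corr <- vapply(seq_len(nrow(sel)), function(r)
    pseudoatom_correction(sel$res_type_i[r], sel$atom_i[r]) +
    pseudoatom_correction(sel$res_type_j[r], sel$atom_j[r]), numeric(1))
  constraint_table(res_i = sel$res_i, atom_i = sel$atom_i,
                   res_j = sel$res_j, atom_j = sel$atom_j,
                   upper = d + pad + corr, lower = lower,
                   res_type_i = sel$res_type_i,
                   res_type_j = sel$res_type_j,
                   weight_class = ifelse(sel$weight == "promoted",
                                         "promoted", "normal"),
                   source = "noe")
}

#' Bin assigned NOESY peaks into strong/medium/weak constraints
#'
#' Manual binning by intensity rank: peaks above the upper tercile of the
#' chosen observable are strong, below the lower tercile weak, medium in
#' between (ties fall to medium), with upper bounds 2.8 / 3.5 / 5.0
#' Angstrom by default.
#'
#' @param assignments a \code{\link{assign_noe_candidates}} result.
#' @param bin_uppers named uppers for \code{strong}, \code{medium},
#'   \code{weak} (Angstrom).
#' @param observable \code{"height"} or \code{"volume"}.
#' @param lower lower bound (default 1.8).
#' @return a \code{\link{constraint_table}} with one row per unambiguous
#'   peak.
#' @export
bin_constraints <- function(assignments,
                            bin_uppers = c(strong = 2.8, medium = 3.5,
                                           weak = 5.0),
                            observable = c("height", "volume"),
                            lower = 1.8) {
  observable <- match.arg(observable)
  sel <- .selected_pairs(assignments, observable)
  if (is.null(sel)) return(empty_constraints())
  q <- stats::quantile(sel$intensity, c(1, 2) / 3, type = 7)
  bin <- ifelse(sel$intensity > q[2], "strong",
                ifelse(sel$intensity < q[1], "weak", "medium"))
  corr <- vapply(seq_len(nrow(sel)), function(r)
    pseudoatom_correction(sel$res_type_i[r], sel$atom_i[r]) +
    pseudoatom_correction(sel$res_type_j[r], sel$atom_j[r]), numeric(1))
  out <- constraint_table(res_i = sel$res_i, atom_i = sel$atom_i,
                          res_j = sel$res_j, atom_j = sel$atom_j,
                          upper = unname(bin_uppers[bin]) + corr,
                          lower = lower,
                          res_type_i = sel$res_type_i,
                          res_type_j = sel$res_type_j,
                          weight_class = ifelse(sel$weight == "promoted",
                                                "promoted", "normal"),
                          source = "noe")
  out$bin <- bin
  out
}
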