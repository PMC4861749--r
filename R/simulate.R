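# experiment definitions for predict-and-confirm simulated peaks:
# which atoms of which residue correlate in each spectrum type

.aromatic_c <- c("CG", "CD1", "CD2", "CE1", "CE2", "CE3", "CZ", "CZ2",
                 "CZ3", "CH2")

aliphatic_carbons <- function(residue_type, atoms) {
  a <- atoms[startsWith(atoms, "C") & atoms != "C"]
  if (toupper(residue_type) %in% c("PHE", "TYR", "TRP", "HIS"))
    a <- setdiff(a, .aromatic_c)
  a
}

aliphatic_protons <- function(atoms) {
  atoms[(startsWith(atoms, "H") | startsWith(atoms, "Q")) &
        !atoms %in% c("HN", "H")]
}

sparky_label <- function(res_type, res_index, atom) {
  one <- tryCatch(bio3d::aa321(res_type), warning = function(w) "X")
  paste0(one, res_index, atom)
}

#' Simulate expected peaks from a shift table
#'
#' One simulated peak per expected correlation of the chosen experiment,
#' e.g. for C(CO)NH the amide (HN, N) of residue i correlated with every
#' aliphatic carbon of residue i-1.  Every peak carries the
#' \code{simulated} flag and the \code{"_s"} label suffix, to be confirmed
#' with \code{\link{center_peak}}.
#'
#' @param shifts a \code{\link{shift_table}}.
#' @param experiment_type one of \code{"N15HSQC"}, \code{"C13HSQC"},
#'   \code{"CCONH"}, \code{"HCCONH"}, \code{"HBHACONH"}.
#' @return an \code{\link{nmr_peaklist}} (2D for HSQC types, 3D
#'   otherwise).
#' @export
simulate_assignments <- function(shifts,
                                 experiment_type = c("N15HSQC", "C13HSQC",
                                                     "CCONH", "HCCONH",
                                                     "HBHACONH")) {
  experiment_type <- match.arg(experiment_type)
  peaks <- list()
  res_ids <- sort(unique(shifts$residue_index))
  atoms_of <- function(i) shifts$atom_name[shifts$residue_index == i]
  type_of <- function(i) shifts$residue_type[shifts$residue_index == i][1]
  add_peak <- function(pos, labels) {
    peaks[[length(peaks) + 1]] <<- nmr_peak(pos, height = 0,
                                            assignment = labels,
                                            flags = "simulated")
  }
  for (i in res_ids) {
    rt <- type_of(i)
    if (experiment_type == "C13HSQC") {
      avail <- atoms_of(i)
      for (h in aliphatic_protons(avail)) {
        if (startsWith(h, "Q")) next
        cc <- attached_heavy(h, avail)
        if (is.na(cc) || !startsWith(cc, "C")) next
        add_peak(c(lookup_shift(shifts, i, h), lookup_shift(shifts, i, cc)),
                 c(sparky_label(rt, i, h), sparky_label(rt, i, cc)))
      }
      next
    }
    hn <- lookup_shift(shifts, i, "HN")
    nn <- lookup_shift(shifts, i, "N")
    if (is.na(hn) || is.na(nn)) next
    if (experiment_type == "N15HSQC") {
      add_peak(c(hn, nn),
               c(sparky_label(rt, i, "HN"), sparky_label(rt, i, "N")))
      next
    }
    # triple-resonance CO-relayed experiments: third dimension from i-1
    if (!(i - 1) %in% res_ids) next
    pt <- type_of(i - 1)
    prev <- atoms_of(i - 1)
    third <- switch(experiment_type,
                    CCONH = aliphatic_carbons(pt, prev),
                    HCCONH = aliphatic_protons(prev),
                    HBHACONH = intersect(prev, c("HA", "HA2", "HA3",
                                                 "HB", "HB2", "HB3",
                                                 "QB")))
    for (a in third)
      add_peak(c(hn, nn, lookup_shift(shifts, i - 1, a)),
               c(sparky_label(rt, i, "HN"), sparky_label(rt, i, "N"),
                 sparky_label(pt, i - 1, a)))
  }
  nmr_peaklist(peaks,
               dimensionality = if (experiment_type %in%
                                    c("N15HSQC", "C13HSQC")) 2L else 3L,
               source_spectrum = experiment_type)
}

#' Merge two overlapping peaks into a pseudoatom peak
#'
#' The peaks must overlap within tolerance on every dimension and their
#' differing assignments must belong to one pseudoatom group (e.g.
#' HB2/HB3).  The merged peak sits at the unweighted mean position and is
#' assigned the DYANA pseudoatom covering both members (QB; QD1/QD2 merge
#' to QQD).
#'
#' @param peak_a,peak_b \code{\link{nmr_peak}}s.
#' @param tolerance ppm overlap tolerance per dimension (recycled).
#' @return the merged \code{\link{nmr_peak}}.
#' @export
merge_pseudoatom <- function(peak_a, peak_b, tolerance = 0.02) {
  nd <- length(peak_a$position)
  stopifnot(length(peak_b$position) == nd)
  tolerance <- rep_len(tolerance, nd)
  if (any(abs(peak_a$position - peak_b$position) > tolerance + 1e-9))
    stop("peaks do not overlap within tolerance; refusing to merge")
  asg <- peak_a$assignment
  for (d in seq_len(nd)) {
    a <- peak_a$assignment[d]; b <- peak_b$assignment[d]
    if (is.na(a) || is.na(b) || a == b) next
    pa <- regmatches(a, regexec("^([A-Za-z][0-9]+)?([A-Za-z0-9]+)$", a))[[1]]
    pb <- regmatches(b, regexec("^([A-Za-z][0-9]+)?([A-Za-z0-9]+)$", b))[[1]]
    base_a <- sub("[0-9]$", "", pa[3]); base_b <- sub("[0-9]$", "", pb[3])
    if (!identical(pa[2], pb[2]) || base_a != base_b || !nzchar(base_a))
      stop("assignments '", a, "' and '", b,
           "' do not belong to one pseudoatom group")
    q <- paste0("Q", sub("^H", "", base_a))
    asg[d] <- paste0(pa[2], q)
  }
  nmr_peak((peak_a$position + peak_b$position) / 2,
           height = mean(c(peak_a$height, peak_b$height), na.rm = TRUE),
           assignment = asg,
           flags = intersect(peak_a$flags, peak_b$flags))
}

#' Assignment completeness report
#'
#' For every residue of the sequence: the fraction of its expected
#' assignable atoms (see \code{\link{residue_roster}}) present in the
#' shift table; for every assigned atom: mean shift, standard deviation
#' and a deviation flag when the sd exceeds the nucleus-class limit
#' (defaults H 0.05 ppm, C/N 0.5 ppm), highlighting suspect assignments.
#'
#' @param shifts a \code{\link{shift_table}}.
#' @param sequence character vector of 3-letter residue types named by
#'   residue index.
#' @param sd_limits deviation-flag limits per nucleus class.
#' @return list with data.frames \code{residues} (index, type, expected,
#'   assigned, completeness) and \code{atoms} (index, atom, shift, sd,
#'   flagged).
#' @export
completeness_report <- function(shifts, sequence,
                                sd_limits = c(H = 0.05, C = 0.5, N = 0.5)) {
  idx <- as.integer(names(sequence))
  res <- data.frame(residue_index = idx,
                    residue_type = unname(sequence),
                    expected = NA_integer_, assigned = NA_integer_,
                    completeness = NA_real_)
  for (r in seq_len(nrow(res))) {
    roster <- residue_roster(res$residue_type[r])
    have <- shifts$atom_name[shifts$residue_index == res$residue_index[r]]
    res$expected[r] <- length(roster)
    res$assigned[r] <- sum(roster %in% have)
    res$completeness[r] <- res$assigned[r] / res$expected[r]
  }
  cls <- ifelse(startsWith(shifts$atom_name, "Q"), "H",
                substr(shifts$atom_name, 1, 1))
  lim <- sd_limits[cls]
  atoms <- data.frame(residue_index = shifts$residue_index,
                      atom_name = shifts$atom_name,
                      shift = shifts$shift, sd = shifts$sd,
                      n_obs = shifts$n_obs,
                      flagged = !is.na(lim) & shifts$sd > lim)
  list(residues = res, atoms = atoms)
}
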