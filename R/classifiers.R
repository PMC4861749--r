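# Per-residue classifiers behind the molecular-viewer color modes.

#' Classify the magnitude of an RDC violation
#'
#' Half-open bins: [0, 1.5) green, [1.5, 3.0) blue, [3.0, 4.5) purple,
#' [4.5, Inf) red (Hz).
#'
#' @param violation_hz absolute violation(s), Hz.
#' @return character class(es).
#' @export
classify_rdc_violation <- function(violation_hz) {
  ifelse(violation_hz >= 4.5, "red",
         ifelse(violation_hz >= 3.0, "purple",
                ifelse(violation_hz >= 1.5, "blue", "green")))
}

#' Classify backbone flexibility from the average Calpha RMSD
#'
#' At or above 2.0 Angstrom the residue is classed saturated red; below
#' that, a green-to-red gradient runs over 0-1.5 Angstrom (fraction =
#' rmsd / 1.5, clamped to 1 between 1.5 and 2.0).
#'
#' @param ca_rmsd average Calpha RMSD(s), Angstrom.
#' @return data.frame \code{(class, fraction)}: class "red" or
#'   "gradient", fraction in [0, 1] (1 for red).
#' @export
classify_flexibility <- function(ca_rmsd) {
  data.frame(class = ifelse(ca_rmsd >= 2.0, "red", "gradient"),
             fraction = pmin(1, ca_rmsd / 1.5))
}

#' Classify residue hydrophobicity
#'
#' Below 10 percent: red; at or above 30 percent: blue; linear
#' red-to-blue gradient between.
#'
#' @param percent hydrophobicity percentage(s), see
#'   \code{\link{hydrophobicity_percent}}.
#' @return data.frame \code{(class, fraction)}: fraction 0 = red,
#'   1 = blue.
#' @export
classify_hydrophobicity <- function(percent) {
  data.frame(class = ifelse(percent < 10, "red",
                            ifelse(percent >= 30, "blue", "gradient")),
             fraction = pmin(1, pmax(0, (percent - 10) / 20)))
}

#' Classify secondary structure from backbone dihedrals
#'
#' Region rule: helix for phi in [-120, -30] and psi in [-80, 40];
#' strand for phi in [-180, -45] and psi in [90, 180) or [-180, -150);
#' loop otherwise.
#'
#' @param phi,psi backbone dihedrals in degrees.
#' @return character vector of \code{"helix"}, \code{"strand"},
#'   \code{"loop"}.
#' @export
classify_secondary_structure <- function(phi, psi) {
  phi <- wrap_angle(phi); psi <- wrap_angle(psi)
  helix <- phi >= -120 & phi <= -30 & psi >= -80 & psi <= 40
  strand <- phi >= -180 & phi <= -45 &
    ((psi >= 90 & psi < 180) | (psi >= -180 & psi < -150))
  out <- ifelse(helix, "helix", ifelse(strand, "strand", "loop"))
  out[is.na(phi) | is.na(psi)] <- "loop"
  out
}

#' Secondary structure from hydrogen-bond patterns
#'
#' DSSP-like override when hydrogens are present: residues involved in
#' i -> i-4 backbone hydrogen bonds are helix; residues whose amides
#' hydrogen-bond to partners at least 5 residues away (ladder pattern)
#' are strand; others fall back to the dihedral rule.
#'
#' @param ensemble an \code{\link{nmr_ensemble}}.
#' @return character vector of classes named by residue index.
#' @export
classify_ss_from_hbonds <- function(ensemble) {
  di <- backbone_dihedrals(ensemble)
  agg <- stats::aggregate(di[, c("phi", "psi")],
                          list(residue_index = di$residue_index),
                          function(a) {
                            a <- a[!is.na(a)] * pi / 180
                            if (!length(a)) return(NA_real_)
                            atan2(mean(sin(a)), mean(cos(a))) * 180 / pi
                          })
  cls <- classify_secondary_structure(agg$phi, agg$psi)
  names(cls) <- agg$residue_index
  hb <- detect_hbonds(ensemble)
  for (r in seq_len(nrow(hb))) {
    d <- hb$donor_res[r]; a <- hb$acceptor_res[r]
    if (d - a == 4) {
      cls[as.character(c(a:d))] <- "helix"
    } else if (abs(d - a) >= 5) {
      cls[as.character(c(d, a))] <- "strand"
    }
  }
  cls
}
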