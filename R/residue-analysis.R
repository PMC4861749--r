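#' Per-residue structure/constraint profile
#'
#' Joins the per-residue validation outputs into one table: Calpha RMSD
#' to the mean structure, circular-mean backbone dihedrals and the
#' secondary-structure class derived from them, hydrophobicity
#' percentage, solvent-accessible surface, NOE constraint counts by
#' range class, worst RDC violation, and the color classes used by the
#' viewer script modes.
#'
#' @param ensemble an \code{\link{nmr_ensemble}}.
#' @param constraints optional \code{\link{constraint_table}}.
#' @param rdc optional \code{\link{rdc_table}}.
#' @param sas_points sphere-sample points per atom passed to
#'   \code{\link{sas_profile}}.
#' @return data.frame of class \code{residue_profile}, one row per
#'   residue.
#' @export
residue_analysis <- function(ensemble, constraints = NULL, rdc = NULL,
                             sas_points = 240) {
  sup <- superpose_ensemble(ensemble)
  prof <- ca_rmsd_profile(sup)
  di <- backbone_dihedrals(ensemble)
  cmean <- function(a) {
    a <- a[!is.na(a)] * pi / 180
    if (!length(a)) return(NA_real_)
    atan2(mean(sin(a)), mean(cos(a))) * 180 / pi
  }
  agg <- stats::aggregate(di[, c("phi", "psi")],
                          list(residue_index = di$residue_index), cmean)
  prof <- merge(prof, agg, by = "residue_index", all.x = TRUE)
  prof$ss_class <- classify_secondary_structure(prof$phi, prof$psi)
  prof$hydrophobicity <- hydrophobicity_percent(prof$residue_type)
  sas <- sas_profile(ensemble, n_points = sas_points)
  prof <- merge(prof, sas[, c("residue_index", "sas")],
                by = "residue_index", all.x = TRUE)
  if (!is.null(constraints)) {
    bars <- noe_bar_chart(constraints, ensemble$sequence)
    prof <- merge(prof, bars, by = "residue_index", all.x = TRUE)
  } else {
    prof$short <- prof$medium <- prof$long <- 0L
  }
  prof$rdc_violation <- NA_real_
  if (!is.null(rdc)) {
    fit <- fit_rdc_tensor(ensemble, rdc)
    v <- stats::aggregate(fit$rdc$violation_hz,
                          list(residue_index = fit$rdc$residue_index),
                          max)
    prof$rdc_violation <- v$x[match(prof$residue_index, v$residue_index)]
  }
  fl <- classify_flexibility(prof$ca_rmsd)
  prof$flex_class <- fl$class; prof$flex_fraction <- fl$fraction
  hy <- classify_hydrophobicity(prof$hydrophobicity)
  prof$hydro_class <- hy$class; prof$hydro_fraction <- hy$fraction
  prof$rdc_class <- ifelse(is.na(prof$rdc_violation), NA_character_,
                           classify_rdc_violation(prof$rdc_violation))
  prof <- prof[order(prof$residue_index), , drop = FALSE]
  rownames(prof) <- NULL
  class(prof) <- c("residue_profile", "data.frame")
  prof
}

.hex2 <- function(x) sprintf("%02x", as.integer(round(x)))

.ss_colors <- c(helix = "0xff0000", strand = "0x0000ff",
                loop = "0x00ff00")
.rdc_colors <- c(green = "0x00ff00", blue = "0x0000ff",
                 purple = "0x800080", red = "0xff0000")

#' Emit a molecular-viewer command script for a color mode
#'
#' Generates deterministic PyMOL-compatible command text implementing
#' the preset shortcut modes: \code{@s} split the ensemble into states,
#' \code{@cs} color by secondary structure (red helix / blue strand /
#' green loop), \code{@ch} color by hydrophobicity (red-to-blue
#' gradient), \code{@cf} color by flexibility (green-to-red gradient,
#' saturated red at high RMSD), \code{@cr} color by RDC violation class,
#' \code{@sl}/\code{@ss}/\code{@sr}/\code{@sc} backbone representations
#' (lines / sticks / ribbon / cartoon), \code{@p} render one distance
#' constraint as a dashed distance object.
#'
#' @param mode one of \code{"@s"}, \code{"@cs"}, \code{"@ch"},
#'   \code{"@cf"}, \code{"@cr"}, \code{"@sl"}, \code{"@ss"},
#'   \code{"@sr"}, \code{"@sc"}, \code{"@p"}.
#' @param profile a \code{\link{residue_analysis}} table (needed by the
#'   color modes).
#' @param constraint one-row \code{\link{constraint_table}} (mode
#'   \code{"@p"}).
#' @param object viewer object name (default \code{"ensemble"}).
#' @return script text, one command per line (single string).
#' @export
emit_viewer_script <- function(mode, profile = NULL, constraint = NULL,
                               object = "ensemble") {
  per_residue <- function(colors, res) {
    paste(sprintf("color %s, %s and resi %d", colors, object, res),
          collapse = "\n")
  }
  txt <- switch(mode,
    "@s" = sprintf("split_states %s", object),
    "@sl" = sprintf("hide everything, %s\nshow lines, %s and backbone",
                    object, object),
    "@ss" = sprintf("hide everything, %s\nshow sticks, %s and backbone",
                    object, object),
    "@sr" = sprintf("hide everything, %s\nshow ribbon, %s",
                    object, object),
    "@sc" = sprintf("hide everything, %s\nshow cartoon, %s",
                    object, object),
    "@cs" = {
      stopifnot(!is.null(profile))
      per_residue(unname(.ss_colors[profile$ss_class]),
                  profile$residue_index)
    },
    "@cf" = {
      stopifnot(!is.null(profile))
      f <- ifelse(profile$flex_class == "red", 1, profile$flex_fraction)
      cols <- sprintf("0x%s%s00", .hex2(255 * f), .hex2(255 * (1 - f)))
      per_residue(cols, profile$residue_index)
    },
    "@ch" = {
      stopifnot(!is.null(profile))
      f <- profile$hydro_fraction
      cols <- sprintf("0x%s00%s", .hex2(255 * (1 - f)), .hex2(255 * f))
      per_residue(cols, profile$residue_index)
    },
    "@cr" = {
      stopifnot(!is.null(profile))
      cls <- profile$rdc_class
      cls[is.na(cls)] <- "green"
      per_residue(unname(.rdc_colors[cls]), profile$residue_index)
    },
    "@p" = {
      stopifnot(!is.null(constraint), nrow(constraint) == 1)
      sprintf(paste0("distance constr, (%s and resi %d and name %s), ",
                     "(%s and resi %d and name %s)\n",
                     "set dash_gap, 0.4, constr"),
              object, constraint$res_i, constraint$atom_i,
              object, constraint$res_j, constraint$atom_j)
    },
    stop("unknown viewer mode: ", mode))
  txt
}
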