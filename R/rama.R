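# torsion angle (degrees, in [-180, 180)) of four points
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  deg <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  wrap_angle(deg)
}

# map any angle to [-180, 180)
wrap_angle <- function(a) a - 360 * floor((a + 180) / 360)

#' Backbone dihedral angles of an ensemble
#'
#' phi(i) = C(i-1)-N(i)-CA(i)-C(i); psi(i) = N(i)-CA(i)-C(i)-N(i+1).
#' Terminal residues have one undefined angle (NA).
#'
#' @param ensemble an \code{\link{nmr_ensemble}}.
#' @return data.frame \code{(residue_index, residue_type, model, phi,
#'   psi)} in degrees, angles in \code{[-180, 180)}.
#' @export
backbone_dihedrals <- function(ensemble) {
  res <- as.integer(names(ensemble$sequence))
  rows <- expand.grid(residue_index = res,
                      model = seq_len(ensemble$n_models))
  rows$residue_type <- unname(ensemble$sequence[as.character(
    rows$residue_index)])
  rows$phi <- NA_real_; rows$psi <- NA_real_
  idx <- function(r, a) {
    v <- atom_row(ensemble, r, a)
    if (length(v)) v[1] else NA_integer_
  }
  for (k in seq_len(nrow(rows))) {
    r <- rows$residue_index[k]; m <- rows$model[k]
    xyz <- model_xyz(ensemble, m)
    iN <- idx(r, "N"); iCA <- idx(r, "CA"); iC <- idx(r, "C")
    if (anyNA(c(iN, iCA, iC))) next
    iCp <- idx(r - 1, "C")
    if (!is.na(iCp))
      rows$phi[k] <- .dihedral(xyz[iCp, ], xyz[iN, ], xyz[iCA, ],
                               xyz[iC, ])
    iNn <- idx(r + 1, "N")
    if (!is.na(iNn))
      rows$psi[k] <- .dihedral(xyz[iN, ], xyz[iCA, ], xyz[iC, ],
                               xyz[iNn, ])
  }
  rows[, c("residue_index", "residue_type", "model", "phi", "psi")]
}

# 1-based voxel index on the 4-degree grid, lower edge inclusive
rama_voxel <- function(angle) {
  pmin(90L, as.integer(floor((wrap_angle(angle) + 180) / 4)) + 1L)
}

#' Ramachandran voxel density of an ensemble
#'
#' Counts (residue, model) phi/psi observations on a 90 x 90 grid of
#' 4 x 4 degree voxels over \code{[-180, 180)}, optionally stratified by
#' residue type or secondary-structure class (classified from each
#' observation's own angles).  Stratified grids sum to the unstratified
#' grid.
#'
#' @param ensemble an \code{\link{nmr_ensemble}}.
#' @param stratifier \code{"all"}, \code{"residue_type"} or
#'   \code{"ss_type"}.
#' @return an object of class \code{rama_grid}: \code{grids} (named list
#'   of 90x90 integer matrices), \code{stratifier}, \code{n_obs}.
#' @export
rama_grid <- function(ensemble, stratifier = c("all", "residue_type",
                                               "ss_type")) {
  stratifier <- match.arg(stratifier)
  di <- backbone_dihedrals(ensemble)
  di <- di[!is.na(di$phi) & !is.na(di$psi), , drop = FALSE]
  strata <- switch(stratifier,
                   all = rep("all", nrow(di)),
                   residue_type = di$residue_type,
                   ss_type = classify_secondary_structure(di$phi, di$psi))
  grids <- list()
  for (s in unique(strata)) {
    g <- matrix(0L, 90, 90)
    sel <- which(strata == s)
    vi <- rama_voxel(di$phi[sel]); vj <- rama_voxel(di$psi[sel])
    for (k in seq_along(sel))
      g[vi[k], vj[k]] <- g[vi[k], vj[k]] + 1L
    grids[[s]] <- g
  }
  structure(list(grids = grids, stratifier = stratifier,
                 n_obs = nrow(di)),
            class = "rama_grid")
}

#' @export
print.rama_grid <- function(x, ...) {
  cat(sprintf("<rama_grid> %d observations, stratifier '%s' (%d grids)\n",
              x$n_obs, x$stratifier, length(x$grids)))
  invisible(x)
}

#' Circular dispersion of a residue's backbone dihedrals
#'
#' Circular standard deviation (degrees) of phi and psi across the
#' models of the ensemble; large values signal conformational
#' heterogeneity at that position.
#'
#' @param ensemble an \code{\link{nmr_ensemble}}.
#' @param residue residue index.
#' @return named numeric \code{c(phi = , psi = )} in degrees (NA when
#'   the angle is undefined).
#' @export
rama_dispersion <- function(ensemble, residue) {
  di <- backbone_dihedrals(ensemble)
  di <- di[di$residue_index == residue, , drop = FALSE]
  circ_sd <- function(a) {
    a <- a[!is.na(a)] * pi / 180
    if (length(a) < 2) return(NA_real_)
    rbar <- sqrt(mean(cos(a))^2 + mean(sin(a))^2)
    sqrt(-2 * log(max(rbar, .Machine$double.eps))) * 180 / pi
  }
  c(phi = circ_sd(di$phi), psi = circ_sd(di$psi))
}
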