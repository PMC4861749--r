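# Bondi van der Waals radii (Angstrom) by element
.vdw_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                P = 1.80)

# deterministic golden-spiral points on the unit sphere
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface per residue
#'
#' Shrake-Rupley sphere sampling: each atom's solvent-expanded sphere
#' (van der Waals radius + probe) is covered with a deterministic
#' golden-spiral point set; a point is accessible when outside every
#' neighboring atom's expanded sphere.  Atom areas are summed per
#' residue.
#'
#' @param ensemble an \code{\link{nmr_ensemble}} (one model used).
#' @param probe_radius solvent probe radius, Angstrom (default 1.4).
#' @param n_points sample points per atom (default 960).
#' @param model model number (default 1).
#' @return data.frame \code{(residue_index, residue_type, sas)} in
#'   Angstrom^2.
#' @export
sas_profile <- function(ensemble, probe_radius = 1.4, n_points = 960,
                        model = 1) {
  xyz <- model_xyz(ensemble, model)
  ele <- ensemble$atoms$element
  rad <- unname(.vdw_radii[ele])
  rad[is.na(rad)] <- 1.7
  rext <- rad + probe_radius
  pts <- sphere_points(n_points)
  n <- nrow(xyz)
  area <- numeric(n)
  for (a in seq_len(n)) {
    d2 <- rowSums((xyz - matrix(xyz[a, ], n, 3, byrow = TRUE))^2)
    nb <- which(d2 < (rext[a] + rext)^2 & seq_len(n) != a)
    sp <- pts * rext[a]
    sp <- sweep(sp, 2, xyz[a, ], `+`)
    acc <- rep(TRUE, n_points)
    for (b in nb) {
      if (!any(acc)) break
      db <- rowSums(sweep(sp, 2, xyz[b, ], `-`)^2)
      acc <- acc & db > rext[b]^2
    }
    area[a] <- 4 * pi * rext[a]^2 * sum(acc) / n_points
  }
  agg <- stats::aggregate(area,
                          list(residue_index =
                                 ensemble$atoms$residue_index), sum)
  data.frame(residue_index = agg$residue_index,
             residue_type = unname(ensemble$sequence[
               as.character(agg$residue_index)]),
             sas = agg$x)
}
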