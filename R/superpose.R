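# n_models x 3N coordinate matrix (x1 y1 z1 x2 ...) for bio3d fitting
.xyz_matrix <- function(ensemble) {
  t(vapply(seq_len(ensemble$n_models), function(m)
    as.vector(t(model_xyz(ensemble, m))),
    numeric(3 * nrow(ensemble$atoms))))
}

#' Superpose an ensemble onto its iteratively refined mean
#'
#' Each model is rigid-body fitted (rotation + translation, no
#' reflection) onto the current mean structure over Calpha atoms; the
#' mean is recomputed and the cycle repeats until it moves less than
#' \code{tol} Angstrom.
#'
#' @param ensemble an \code{\link{nmr_ensemble}} with CA atoms.
#' @param tol convergence threshold on the mean coordinates (default
#'   1e-6 Angstrom).
#' @param max_iter iteration cap.
#' @return list with \code{ensemble} (superposed) and \code{mean}
#'   (n_atoms x 3 matrix).
#' @export
superpose_ensemble <- function(ensemble, tol = 1e-6, max_iter = 100) {
  ca <- which(ensemble$atoms$atom_name == "CA")
  if (!length(ca)) stop("no CA atoms in ensemble")
  ca_inds <- as.vector(vapply(ca, function(a) (3 * a - 2):(3 * a),
                              numeric(3)))
  m <- .xyz_matrix(ensemble)
  if (ensemble$n_models == 1) {
    ensemble_mean <- model_xyz(ensemble, 1)
    return(list(ensemble = ensemble, mean = ensemble_mean))
  }
  ref <- m[1, ]
  for (it in seq_len(max_iter)) {
    fitted <- bio3d::fit.xyz(fixed = ref, mobile = m,
                             fixed.inds = ca_inds, mobile.inds = ca_inds)
    new_ref <- colMeans(fitted)
    shift <- max(abs(new_ref - ref))
    m <- fitted
    ref <- new_ref
    if (shift < tol) break
  }
  xyz <- array(NA_real_, dim = dim(ensemble$xyz))
  for (mm in seq_len(ensemble$n_models))
    xyz[, , mm] <- matrix(m[mm, ], ncol = 3, byrow = TRUE)
  out <- ensemble
  out$xyz <- xyz
  list(ensemble = out, mean = matrix(ref, ncol = 3, byrow = TRUE))
}

#' Per-residue Calpha RMSD to the mean structure
#'
#' @param superposed result of \code{\link{superpose_ensemble}} (an
#'   unsuperposed \code{\link{nmr_ensemble}} is superposed first).
#' @return data.frame \code{(residue_index, residue_type, ca_rmsd)} in
#'   Angstrom.
#' @export
ca_rmsd_profile <- function(superposed) {
  if (inherits(superposed, "nmr_ensemble"))
    superposed <- superpose_ensemble(superposed)
  ens <- superposed$ensemble
  mn <- superposed$mean
  ca <- which(ens$atoms$atom_name == "CA")
  data.frame(residue_index = ens$atoms$residue_index[ca],
             residue_type = ens$atoms$residue_type[ca],
             ca_rmsd = vapply(ca, function(a) {
               d2 <- vapply(seq_len(ens$n_models), function(m)
                 sum((ens$xyz[a, , m] - mn[a, ])^2), numeric(1))
               sqrt(mean(d2))
             }, numeric(1)))
}
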