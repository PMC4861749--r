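#' Residual dipolar coupling table
#'
#' @param residue_index integer vector.
#' @param atom_1,atom_2 the coupled atom pair (e.g. "N", "HN").
#' @param d_obs observed couplings, Hz.
#' @param d_calc back-calculated couplings (filled by
#'   \code{\link{fit_rdc_tensor}}).
#' @return a data.frame of class \code{rdc_table}.
#' @export
rdc_table <- function(residue_index, atom_1, atom_2, d_obs,
                      d_calc = NA_real_) {
  if (!all(is.finite(d_obs))) stop("couplings must be finite")
  df <- data.frame(residue_index = as.integer(residue_index),
                   atom_1 = toupper(atom_1), atom_2 = toupper(atom_2),
                   d_obs = as.numeric(d_obs),
                   d_calc = as.numeric(rep_len(d_calc,
                                               length(residue_index))),
                   stringsAsFactors = FALSE)
  class(df) <- c("rdc_table", "data.frame")
  df
}

#' Read / write an RDC TSV table
#'
#' Columns: \code{residue_index}, \code{atom_1}, \code{atom_2},
#' \code{d_obs} (Hz), optionally \code{d_calc}.
#'
#' @param path file path.
#' @return \code{read_rdc}: an \code{\link{rdc_table}}.
#' @export
read_rdc <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  rdc_table(df$residue_index, df$atom_1, df$atom_2, df$d_obs,
            if ("d_calc" %in% names(df)) df$d_calc else NA_real_)
}

#' @rdname read_rdc
#' @param rdc an \code{\link{rdc_table}}.
#' @export
write_rdc <- function(rdc, path) {
  utils::write.table(rdc, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# design matrix row for a unit bond vector: coefficients of
# (Sxx, Syy, Sxy, Sxz, Syz) with Szz = -Sxx - Syy
.saupe_row <- function(v) {
  c(v[1]^2 - v[3]^2, v[2]^2 - v[3]^2,
    2 * v[1] * v[2], 2 * v[1] * v[3], 2 * v[2] * v[3])
}

.saupe_matrix <- function(s) {
  matrix(c(s[1], s[3], s[4],
           s[3], s[2], s[5],
           s[4], s[5], -s[1] - s[2]), 3, 3)
}

#' Fit an RDC alignment tensor to a structure
#'
#' Solves the linear system D = A s for the 5 independent Saupe elements
#' by singular-value decomposition of the design matrix built from unit
#' bond vectors, back-calculates couplings, and reports the Pearson
#' correlation and the quality factor
#' Q = rms(D_calc - D_obs) / rms(D_obs).
#'
#' @param ensemble an \code{\link{nmr_ensemble}}.
#' @param rdc an \code{\link{rdc_table}} with at least 5 records.
#' @param model model number, or \code{"mean"} (default) for the mean
#'   structure of the superposed ensemble.
#' @return list of class \code{rdc_fit}: \code{tensor} (an
#'   \code{alignment_tensor}: saupe 5-vector, 3x3 matrix S, principal
#'   values ascending by magnitude, axial and rhombicity), \code{rdc}
#'   (records with \code{d_calc} and \code{violation_hz} filled),
#'   \code{pearson_r}, \code{q_factor}.
#' @export
fit_rdc_tensor <- function(ensemble, rdc, model = "mean") {
  if (nrow(rdc) < 5)
    stop("need at least 5 RDC records to fit a 5-element tensor, got ",
         nrow(rdc))
  xyz <- if (identical(model, "mean"))
    superpose_ensemble(ensemble)$mean else model_xyz(ensemble, model)
  A <- matrix(NA_real_, nrow(rdc), 5)
  for (r in seq_len(nrow(rdc))) {
    i1 <- atom_row(ensemble, rdc$residue_index[r], rdc$atom_1[r])
    i2 <- atom_row(ensemble, rdc$residue_index[r], rdc$atom_2[r])
    if (!length(i1) || !length(i2))
      stop("RDC record ", r, ": atom pair not found in structure")
    v <- xyz[i2[1], ] - xyz[i1[1], ]
    A[r, ] <- .saupe_row(v / sqrt(sum(v^2)))
  }
  sv <- svd(A)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  if (rank < 5)
    stop("rank-deficient RDC system (rank ", rank,
         "): bond vectors too collinear to determine the tensor")
  s <- sv$v %*% ((t(sv$u) %*% rdc$d_obs) / sv$d)
  s <- as.numeric(s)
  S <- .saupe_matrix(s)
  ev <- eigen(S, symmetric = TRUE)
  o <- order(abs(ev$values))
  vals <- ev$values[o]
  tensor <- structure(list(saupe = s, S = S, principal_values = vals,
                           axial = vals[3],
                           rhombicity = (vals[2] - vals[1]) / vals[3]),
                      class = "alignment_tensor")
  rdc$d_calc <- as.numeric(A %*% s)
  rdc$violation_hz <- abs(rdc$d_calc - rdc$d_obs)
  structure(list(tensor = tensor, rdc = rdc,
                 pearson_r = stats::cor(rdc$d_obs, rdc$d_calc),
                 q_factor = sqrt(mean((rdc$d_calc - rdc$d_obs)^2)) /
                   sqrt(mean(rdc$d_obs^2))),
            class = "rdc_fit")
}

#' @export
print.rdc_fit <- function(x, ...) {
  cat(sprintf("<rdc_fit> %d couplings, Q = %.4f, r = %.4f\n",
              nrow(x$rdc), x$q_factor, x$pearson_r))
  invisible(x)
}

#' Back-calculate RDCs from a tensor
#'
#' @param ensemble an \code{\link{nmr_ensemble}}.
#' @param rdc an \code{\link{rdc_table}} (atom pairs used).
#' @param saupe 5-vector (Sxx, Syy, Sxy, Sxz, Syz).
#' @param model model number (default 1).
#' @return the \code{rdc_table} with \code{d_calc} filled.
#' @export
rdc_forward <- function(ensemble, rdc, saupe, model = 1) {
  xyz <- model_xyz(ensemble, model)
  for (r in seq_len(nrow(rdc))) {
    i1 <- atom_row(ensemble, rdc$residue_index[r], rdc$atom_1[r])
    i2 <- atom_row(ensemble, rdc$residue_index[r], rdc$atom_2[r])
    v <- xyz[i2[1], ] - xyz[i1[1], ]
    rdc$d_calc[r] <- sum(.saupe_row(v / sqrt(sum(v^2))) * saupe)
  }
  rdc
}
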