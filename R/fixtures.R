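# Seed-deterministic synthetic-data generators.  Every generator returns
# its ground truth alongside the data so tests can compare against it.

with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# next-atom placement from bond length r, bond angle theta and dihedral
# chi (degrees) relative to reference atoms a-b-c
.nerf <- function(a, b, c, r, theta, chi) {
  th <- theta * pi / 180; ch <- chi * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-r * cos(th), r * sin(th) * cos(ch), -r * sin(th) * sin(ch))
  c + bc * d[1] + m * d[2] + n * d[3]
}

#' Ideal alpha-helix ensemble
#'
#' Polyalanine backbone built from standard covalent geometry at
#' phi = -57, psi = -47 degrees (omega 180), with carbonyl O, amide H
#' (bisector placement) and HA.  Each model adds independent Gaussian
#' coordinate jitter.
#'
#' @param n_residues chain length.
#' @param n_models number of models (default 20, the usual deposited
#'   bundle size).
#' @param jitter per-coordinate Gaussian sd in Angstrom (default 0).
#' @param seed RNG seed for the jitter.
#' @param phi,psi backbone dihedrals in degrees.
#' @return an \code{\link{nmr_ensemble}}.
#' @export
make_helix_ensemble <- function(n_residues, n_models = 20, jitter = 0,
                                seed = 1, phi = -57, psi = -47) {
  stopifnot(n_residues >= 2)
  N <- CA <- C <- O <- H <- HA <- matrix(NA_real_, n_residues, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  ang <- 111.0 * pi / 180
  C[1, ] <- CA[1, ] + 1.525 * c(-cos(ang), sin(ang), 0)
  for (i in 2:n_residues) {
    N[i, ] <- .nerf(N[i - 1, ], CA[i - 1, ], C[i - 1, ], 1.329, 116.2,
                    psi)
    CA[i, ] <- .nerf(CA[i - 1, ], C[i - 1, ], N[i, ], 1.458, 121.7, 180)
    C[i, ] <- .nerf(C[i - 1, ], N[i, ], CA[i, ], 1.525, 111.0, phi)
  }
  for (i in seq_len(n_residues)) {
    O[i, ] <- .nerf(N[i, ], CA[i, ], C[i, ], 1.231, 120.8, psi + 180)
    u1 <- N[i, ] - CA[i, ]; u1 <- u1 / sqrt(sum(u1^2))
    u2 <- C[i, ] - CA[i, ]; u2 <- u2 / sqrt(sum(u2^2))
    perp <- c(u1[2] * u2[3] - u1[3] * u2[2],
              u1[3] * u2[1] - u1[1] * u2[3],
              u1[1] * u2[2] - u1[2] * u2[1])
    v <- -(u1 + u2) + perp
    HA[i, ] <- CA[i, ] + 1.09 * v / sqrt(sum(v^2))
    if (i >= 2) {
      w1 <- C[i - 1, ] - N[i, ]; w1 <- w1 / sqrt(sum(w1^2))
      w2 <- CA[i, ] - N[i, ]; w2 <- w2 / sqrt(sum(w2^2))
      hb <- -(w1 + w2)
      H[i, ] <- N[i, ] + 1.01 * hb / sqrt(sum(hb^2))
    }
  }
  rows <- list()
  coords <- list()
  for (i in seq_len(n_residues)) {
    names_i <- c("N", if (i >= 2) "HN", "CA", "HA", "C", "O")
    xyz_i <- rbind(N[i, ], if (i >= 2) H[i, ], CA[i, ], HA[i, ], C[i, ],
                   O[i, ])
    rows[[i]] <- data.frame(residue_index = i, residue_type = "ALA",
                            atom_name = names_i,
                            element = .element_of(names_i),
                            stringsAsFactors = FALSE)
    coords[[i]] <- xyz_i
  }
  atoms <- do.call(rbind, rows)
  base <- do.call(rbind, coords)
  xyz <- array(NA_real_, dim = c(nrow(atoms), 3, n_models))
  with_seed(seed, {
    for (m in seq_len(n_models))
      xyz[, , m] <- base + if (jitter > 0)
        matrix(stats::rnorm(length(base), sd = jitter), nrow(base), 3)
      else 0
  })
  nmr_ensemble(atoms, xyz)
}

#' Synthetic gridded spectrum from planted peaks
#'
#' Sum of separable Gaussian or Lorentzian lineshapes plus optional
#' Gaussian noise on the full grid.
#'
#' @param positions matrix of peak positions (rows = peaks, columns =
#'   ppm per dimension).
#' @param heights peak heights.
#' @param axes list of \code{\link{nmr_axis}}.
#' @param noise_sigma Gaussian noise sd (intensity units).
#' @param seed RNG seed.
#' @param lineshape \code{"gaussian"} or \code{"lorentzian"}.
#' @param linewidths per-dimension width parameter in ppm (default
#'   2 grid steps).
#' @param name spectrum label.
#' @return an \code{\link{nmr_spectrum}}.
#' @export
make_spectrum <- function(positions, heights, axes, noise_sigma = 0,
                          seed = 1,
                          lineshape = c("gaussian", "lorentzian"),
                          linewidths = NULL, name = "synthetic") {
  lineshape <- match.arg(lineshape)
  positions <- matrix(positions, ncol = length(axes))
  np <- vapply(axes, function(a) a$n_points, integer(1))
  if (is.null(linewidths))
    linewidths <- vapply(axes, function(a) 2 * axis_step(a), numeric(1))
  data <- array(0, dim = np)
  shape <- function(x) if (lineshape == "gaussian")
    exp(-0.5 * x^2) else 1 / (1 + x^2)
  for (p in seq_len(nrow(positions))) {
    profs <- lapply(seq_along(axes), function(d) {
      ppm <- axis_ppm(axes[[d]], seq_len(np[d]))
      shape((ppm - positions[p, d]) / linewidths[d])
    })
    contrib <- Reduce(`%o%`, profs)
    data <- data + heights[p] * contrib
  }
  if (noise_sigma > 0)
    data <- data + with_seed(seed,
      array(stats::rnorm(prod(np), sd = noise_sigma), dim = np))
  nmr_spectrum(axes, data, name = name)
}

#' Synthetic NOESY peak set from a structure
#'
#' Enumerates all proton pairs of one model closer than
#' \code{max_distance} and builds an assigned 2D NOESY peak list with
#' intensities \code{c * r^-k}, together with a synthetic shift table
#' (distinct proton shifts on a 0.05-ppm grid) and the ground-truth
#' pair/distance table.  Optional orphan noise peaks are planted at
#' positions matching no shift pair and flagged in the truth table.
#'
#' @param ensemble an \code{\link{nmr_ensemble}} (model 1 used).
#' @param c calibration constant (default 1e6).
#' @param k distance exponent (default 6).
#' @param max_distance Angstrom cutoff for generated cross peaks
#'   (default 5.5).
#' @param seed RNG seed (shift scrambling, noise placement).
#' @param n_noise number of planted orphan noise peaks (default 0).
#' @return list: \code{peaks} (\code{\link{nmr_peaklist}}),
#'   \code{truth} (data.frame incl. \code{is_noise}), \code{shifts}
#'   (\code{\link{shift_table}}), \code{calibration}
#'   (\code{\link{noe_calibration}}).
#' @export
make_noe_set <- function(ensemble, c = 1e6, k = 6, max_distance = 5.5,
                         seed = 1, n_noise = 0) {
  hs <- which(ensemble$atoms$element == "H")
  if (length(hs) < 2) stop("ensemble has too few protons")
  at <- ensemble$atoms[hs, , drop = FALSE]
  xyz <- model_xyz(ensemble, 1)[hs, , drop = FALSE]
  shifts_ppm <- with_seed(seed, {
    grid <- seq(0.5, 0.5 + 0.05 * (length(hs) * 3), by = 0.05)
    sample(grid, length(hs))
  })
  shifts <- shift_table(at$residue_index, at$residue_type, at$atom_name,
                        shifts_ppm)
  dd <- as.matrix(stats::dist(xyz))
  pairs <- which(upper.tri(dd) & dd < max_distance, arr.ind = TRUE)
  truth <- data.frame(res_i = at$residue_index[pairs[, 1]],
                      atom_i = at$atom_name[pairs[, 1]],
                      res_j = at$residue_index[pairs[, 2]],
                      atom_j = at$atom_name[pairs[, 2]],
                      r = dd[pairs],
                      stringsAsFactors = FALSE)
  truth$intensity <- c * truth$r^(-k)
  truth$is_noise <- FALSE
  peaks <- lapply(seq_len(nrow(truth)), function(p) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    nmr_peak(base::c(shifts_ppm[i], shifts_ppm[j]),
             height = truth$intensity[p],
             assignment = base::c(sparky_label(at$residue_type[i],
                                               at$residue_index[i],
                                               at$atom_name[i]),
                                  sparky_label(at$residue_type[j],
                                               at$residue_index[j],
                                               at$atom_name[j])))
  })
  if (n_noise > 0) {
    noise <- with_seed(seed + 1, {
      lapply(seq_len(n_noise), function(q)
        nmr_peak(stats::runif(2, 15, 20),   # far from every real shift
                 height = c * max_distance^(-k) *
                   stats::runif(1, 0.1, 0.9)))
    })
    peaks <- base::c(peaks, noise)
    truth <- rbind(truth,
                   data.frame(res_i = NA, atom_i = NA, res_j = NA,
                              atom_j = NA, r = NA, intensity = NA,
                              is_noise = rep(TRUE, n_noise)))
  }
  list(peaks = nmr_peaklist(peaks, 2, source_spectrum = "synthetic_noesy"),
       truth = truth, shifts = shifts,
       calibration = noe_calibration(c, k))
}

#' Synthetic RDC set from a structure and a known tensor
#'
#' Back-calculates N-HN couplings from the Saupe tensor on model 1 and
#' adds optional Gaussian noise.
#'
#' @param ensemble an \code{\link{nmr_ensemble}} with amide protons.
#' @param saupe 5-vector (Sxx, Syy, Sxy, Sxz, Syz); units become Hz.
#' @param noise_sigma Gaussian noise sd, Hz.
#' @param seed RNG seed.
#' @return list: \code{rdc} (\code{\link{rdc_table}} with noisy
#'   \code{d_obs}), \code{saupe} (the generating tensor).
#' @export
make_rdc_set <- function(ensemble, saupe, noise_sigma = 0, seed = 1) {
  res <- as.integer(names(ensemble$sequence))
  keep <- vapply(res, function(r)
    length(atom_row(ensemble, r, "N")) > 0 &&
    length(atom_row(ensemble, r, "HN")) > 0, logical(1))
  res <- res[keep]
  tab <- rdc_table(res, "N", "HN", d_obs = 0)
  tab <- rdc_forward(ensemble, tab, saupe)
  tab$d_obs <- tab$d_calc + if (noise_sigma > 0)
    with_seed(seed, stats::rnorm(nrow(tab), sd = noise_sigma)) else 0
  tab$d_calc <- NA_real_
  list(rdc = tab, saupe = saupe)
}

#' Synthetic spectral series
#'
#' \code{decay}: per-residue heights \code{I0 * exp(-R * t)} with rates
#' drawn uniformly from \code{r_range}, plus proportional Gaussian
#' noise.  \code{titration}: per-residue shifts moving monotonically
#' with the condition by a saturating binding curve.
#'
#' @param kind \code{"decay"} or \code{"titration"}.
#' @param n_residues number of residues.
#' @param conditions condition values (defaults: 8 times 0..1.4 s for
#'   decay, molar ratios 0..2 for titration).
#' @param i0 decay amplitude (default 100).
#' @param r_range decay-rate range, 1/s (default 0.3-1.5, typical
#'   amide R2 magnitudes sampled over about two time constants).
#' @param noise relative Gaussian noise (fraction of I0 / of total shift
#'   change).
#' @param seed RNG seed.
#' @return list: \code{series} (\code{\link{series_table}}),
#'   \code{truth} (data.frame of generating parameters).
#' @export
make_series <- function(kind = c("decay", "titration"), n_residues = 10,
                        conditions = NULL, i0 = 100,
                        r_range = c(0.3, 1.5), noise = 0, seed = 1) {
  kind <- match.arg(kind)
  if (is.null(conditions))
    conditions <- if (kind == "decay") seq(0, 1.4, by = 0.2)
                  else seq(0, 2, by = 0.25)
  with_seed(seed, {
    if (kind == "decay") {
      rates <- stats::runif(n_residues, r_range[1], r_range[2])
      v <- outer(rates, conditions, function(r, t) i0 * exp(-r * t))
      if (noise > 0)
        v <- v + matrix(stats::rnorm(length(v), sd = noise * i0),
                        nrow(v))
      rownames(v) <- seq_len(n_residues)
      list(series = series_table(conditions, v, observable = "height",
                                 condition_name = "time_s"),
           truth = data.frame(residue = seq_len(n_residues), I0 = i0,
                              R = rates))
    } else {
      base <- stats::runif(n_residues, 7, 9)
      delta <- stats::runif(n_residues, 0.05, 0.3)
      kd <- 0.5
      v <- outer(seq_len(n_residues), conditions, function(i, x)
        base[i] + delta[i] * x / (x + kd))
      if (noise > 0)
        v <- v + matrix(stats::rnorm(length(v), sd = noise * mean(delta)),
                        nrow(v))
      rownames(v) <- seq_len(n_residues)
      list(series = series_table(conditions, v, observable = "shift_H",
                                 condition_name = "molar_ratio"),
           truth = data.frame(residue = seq_len(n_residues), base = base,
                              delta = delta, kd = kd))
    }
  })
}
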