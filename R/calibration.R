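#' NOE intensity-to-distance calibration
#'
#' NOESY cross-peak intensities fall off approximately as \code{r^-k}
#' (k = 6 for rigid molecules; values down to 3 accommodate dynamics and
#' spin diffusion).  The calibration pins a reference percentile of the
#' absolute intensities to a reference distance:
#' \code{c = I_p * d_ref^k}, so \code{d(I) = (c / I)^(1/k)}.
#'
#' @param intensities signed peak intensities (at least 5 with positive
#'   magnitude).
#' @param k distance exponent in \code{[3, 6]} (default 6).
#' @param reference list with \code{p} (percentile of |intensity|,
#'   default 0.5 = median) and \code{d_ref} (distance in Angstrom assigned
#'   to that percentile, default 3.0).
#' @return an object of class \code{noe_calibration}: \code{c}, \code{k},
#'   \code{reference}.
#' @export
calibrate <- function(intensities, k = 6,
                      reference = list(p = 0.5, d_ref = 3.0)) {
  if (k < 3 || k > 6) stop("exponent k must lie in [3, 6]")
  if (!any(is.finite(intensities) & intensities > 0))
    stop("all intensities are non-positive")
  ai <- abs(intensities[is.finite(intensities)])
  ai <- ai[ai > 0]
  if (length(ai) < 5)
    stop("need at least 5 positive intensities to calibrate, got ",
         length(ai))
  ip <- unname(stats::quantile(ai, probs = reference$p, type = 7))
  noe_calibration(ip * reference$d_ref^k, k, reference)
}

#' Construct a calibration from a known constant
#'
#' @param c calibration constant (intensity * Angstrom^k), > 0.
#' @param k distance exponent in \code{[3, 6]}.
#' @param reference optional provenance (percentile/distance pair).
#' @return an object of class \code{noe_calibration}.
#' @export
noe_calibration <- function(c, k = 6, reference = NULL) {
  stopifnot(c > 0, k >= 3, k <= 6)
  structure(list(c = as.numeric(c), k = as.numeric(k),
                 reference = reference),
            class = "noe_calibration")
}

#' Convert NOE intensity to distance under a calibration
#'
#' @param calibration a \code{\link{noe_calibration}}.
#' @param intensity signed intensity (magnitude used).
#' @return distance(s) in Angstrom, strictly decreasing in |intensity|.
#' @export
noe_distance <- function(calibration, intensity) {
  (calibration$c / abs(intensity))^(1 / calibration$k)
}

#' @export
print.noe_calibration <- function(x, ...) {
  cat(sprintf("<noe_calibration> c = %.6g, k = %g\n", x$c, x$k))
  invisible(x)
}

#' Estimate the noise intensity threshold of a NOESY peak set
#'
#' Inverts the calibration at the distance cutoff beyond which cross
#' peaks are not expected (default 5.5 Angstrom): \code{I_cut =
#' c / d_cut^k}.  Peaks are ranked by absolute intensity and partitioned
#' into a robust zone (at least as intense as the \code{d_robust}
#' equivalent, default 4.5 Angstrom), a noise zone (below \code{I_cut})
#' and a mixed zone in between, where real peaks and noise coexist.
#'
#' @param intensities signed peak intensities.
#' @param calibration a \code{\link{noe_calibration}}.
#' @param d_cut noise cutoff distance, Angstrom (default 5.5).
#' @param d_robust robust-zone distance, Angstrom (default 4.5).
#' @return an object of class \code{intensity_threshold}: \code{I_cut},
#'   \code{d_cut}, \code{I_robust}, \code{zones} (factor per input peak:
#'   robust/mixed/noise) and \code{counts}.
#' @export
estimate_noise_threshold <- function(intensities, calibration,
                                     d_cut = 5.5, d_robust = 4.5) {
  i_cut <- calibration$c / d_cut^calibration$k
  i_rob <- calibration$c / d_robust^calibration$k
  ai <- abs(intensities)
  zones <- factor(ifelse(ai >= i_rob, "robust",
                         ifelse(ai < i_cut, "noise", "mixed")),
                  levels = c("robust", "mixed", "noise"))
  structure(list(I_cut = i_cut, d_cut = d_cut, I_robust = i_rob,
                 d_robust = d_robust, zones = zones,
                 counts = table(zones)),
            class = "intensity_threshold")
}

#' @export
print.intensity_threshold <- function(x, ...) {
  cat(sprintf("<intensity_threshold> I_cut = %.6g at %.2f A (%s)\n",
              x$I_cut, x$d_cut,
              paste(names(x$counts), as.integer(x$counts), sep = ":",
                    collapse = " ")))
  invisible(x)
}
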