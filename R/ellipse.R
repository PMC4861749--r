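#' Statistical chemical-shift ellipse
#'
#' Confidence ellipse of a bivariate Gaussian over (1H, 13C) chemical
#' shifts, of the kind drawn over RNA spectra to delineate the expected
#' region for a base/atom class.  The ellipse is the eigen-decomposition
#' of the covariance scaled by the chi-square quantile with 2 degrees of
#' freedom.
#'
#' @param center length-2 mean shift (ppm).
#' @param covariance 2x2 positive-definite covariance (ppm^2).
#' @param confidence coverage probability in (0, 1).
#' @return an object of class \code{shift_ellipse} with fields
#'   \code{center}, \code{covariance}, \code{confidence}, \code{q}
#'   (chi-square quantile), \code{semi_axes} (descending) and
#'   \code{angle_deg} (major-axis angle).
#' @export
rna_statistical_ellipse <- function(center, covariance, confidence) {
  stopifnot(length(center) == 2, all(dim(covariance) == c(2, 2)),
            confidence > 0, confidence < 1)
  covariance <- (covariance + t(covariance)) / 2
  ev <- eigen(covariance, symmetric = TRUE)
  if (any(ev$values <= 0))
    stop("covariance must be positive-definite")
  q <- stats::qchisq(confidence, df = 2)
  structure(list(center = as.numeric(center), covariance = covariance,
                 confidence = confidence, q = q,
                 semi_axes = sqrt(ev$values * q),
                 angle_deg = atan2(ev$vectors[2, 1],
                                   ev$vectors[1, 1]) * 180 / pi),
            class = "shift_ellipse")
}

#' Test whether a peak lies inside a shift ellipse
#'
#' Membership is squared Mahalanobis distance at most the ellipse's
#' chi-square quantile.
#'
#' @param peak an \code{\link{nmr_peak}} or a length-2 ppm position.
#' @param ellipse a \code{\link{rna_statistical_ellipse}}.
#' @return logical.
#' @export
classify_peak_in_ellipse <- function(peak, ellipse) {
  pos <- if (inherits(peak, "nmr_peak")) peak$position else as.numeric(peak)
  stopifnot(length(pos) == 2)
  m2 <- stats::mahalanobis(matrix(pos, 1), ellipse$center,
                           ellipse$covariance)
  unname(m2 <= ellipse$q)
}
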