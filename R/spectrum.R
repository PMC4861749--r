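#' NMR spectrum axis
#'
#' An axis describes the ppm calibration of one dimension of a gridded
#' frequency-domain spectrum: the observed nucleus, the number of grid
#' points, the spectral width (Hz), the spectrometer frequency for that
#' nucleus (MHz) and the carrier position (ppm).  The ppm scale follows the
#' standard display convention: ppm decreases with increasing grid index,
#' with the first point at the downfield (high-ppm) edge.
#'
#' @param nucleus nucleus label, e.g. \code{"1H"}, \code{"15N"}, \code{"13C"}.
#' @param n_points number of (real) data points along the axis.
#' @param spectral_width sweep width in Hz.
#' @param spectrometer_freq spectrometer frequency for this nucleus in MHz.
#' @param center_ppm carrier position in ppm.
#' @return an object of class \code{nmr_axis}.
#' @export
nmr_axis <- function(nucleus, n_points, spectral_width, spectrometer_freq,
                     center_ppm) {
  stopifnot(is.character(nucleus), length(nucleus) == 1L,
            n_points >= 1, spectral_width > 0, spectrometer_freq > 0)
  structure(list(nucleus = nucleus,
                 n_points = as.integer(n_points),
                 spectral_width = as.numeric(spectral_width),
                 spectrometer_freq = as.numeric(spectrometer_freq),
                 center_ppm = as.numeric(center_ppm)),
            class = "nmr_axis")
}

#' Convert a grid index to ppm
#'
#' Index 1 sits at the downfield edge; ppm decreases strictly with index.
#' Fractional indices are allowed (used by sub-grid peak refinement).
#'
#' @param axis an \code{nmr_axis}.
#' @param index grid index (1-based, possibly fractional).
#' @return chemical shift(s) in ppm.
#' @export
axis_ppm <- function(axis, index) {
  sw_ppm <- axis$spectral_width / axis$spectrometer_freq
  step <- sw_ppm / axis$n_points
  axis$center_ppm + sw_ppm / 2 - (index - 1) * step - step / 2
}

#' Convert ppm to the nearest grid index
#'
#' @param axis an \code{nmr_axis}.
#' @param ppm chemical shift(s) in ppm.
#' @param clamp clamp result into \code{[1, n_points]} (default TRUE).
#' @return integer grid index (nearest grid point).
#' @export
axis_index <- function(axis, ppm, clamp = TRUE) {
  sw_ppm <- axis$spectral_width / axis$spectrometer_freq
  step <- sw_ppm / axis$n_points
  i <- round((axis$center_ppm + sw_ppm / 2 - step / 2 - ppm) / step + 1)
  if (clamp) i <- pmin(pmax(i, 1), axis$n_points)
  as.integer(i)
}

# ppm grid step (positive number; scale itself decreases with index)
axis_step <- function(axis) {
  axis$spectral_width / axis$spectrometer_freq / axis$n_points
}

# nucleus class letter used for tolerance lookup: "H", "N" or "C"
nucleus_class <- function(nucleus) {
  sub("^[0-9]*", "", nucleus)
}

#' Gridded NMR spectrum
#'
#' A dense real intensity grid with per-axis ppm calibration.  Axis 1 is
#' the first array dimension.
#'
#' @param axes list of \code{nmr_axis} objects (2 to 4).
#' @param data numeric array whose \code{dim} matches the axes' point counts.
#'   A 1-row or vector input for a 2D spectrum is coerced with
#'   \code{array()}.
#' @param name spectrum label.
#' @return an object of class \code{nmr_spectrum}.
#' @export
nmr_spectrum <- function(axes, data, name = "") {
  stopifnot(length(axes) >= 1, length(axes) <= 4)
  np <- vapply(axes, function(a) a$n_points, integer(1))
  data <- array(as.numeric(data), dim = np)
  if (!all(is.finite(data))) stop("spectrum data must be finite")
  structure(list(axes = axes, data = data, name = name),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum '%s'> %s\n", x$name,
              paste(vapply(x$axes, function(a)
                sprintf("%s[%d]", a$nucleus, a$n_points), character(1)),
                collapse = " x ")))
  invisible(x)
}

#' @export
dim.nmr_spectrum <- function(x) dim(x$data)

# ppm position of a (possibly fractional) multi-index
spectrum_ppm <- function(spectrum, index) {
  vapply(seq_along(spectrum$axes), function(d)
    axis_ppm(spectrum$axes[[d]], index[d]), numeric(1))
}
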