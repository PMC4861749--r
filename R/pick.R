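#' Peak-picking parameters
#'
#' @param threshold contour floor: minimum \code{|intensity|} for a pick
#'   (must be > 0).
#' @param tolerances ppm match tolerances per nucleus class; defaults
#'   H 0.02, N 0.2, C 0.2.
#' @param min_spectra_support number of spectra that must share a spin
#'   system root before its peaks are considered real (default 2).
#' @return an object of class \code{pick_params}.
#' @export
pick_params <- function(threshold = 0,
                        tolerances = c(H = 0.02, N = 0.2, C = 0.2),
                        min_spectra_support = 2L) {
  stopifnot(all(tolerances > 0), min_spectra_support >= 1)
  structure(list(threshold = threshold, tolerances = tolerances,
                 min_spectra_support = as.integer(min_spectra_support)),
            class = "pick_params")
}

tol_for_nucleus <- function(params, nucleus) {
  cl <- nucleus_class(nucleus)
  tl <- params$tolerances
  if (!cl %in% names(tl)) cl <- "C"       # heteronucleus fallback
  unname(tl[cl])
}

# shift an array by integer offset, filling exposed borders
shift_array <- function(a, offset, fill = -Inf) {
  dm <- dim(a)
  idx <- lapply(seq_along(dm), function(d) {
    i <- seq_len(dm[d]) - offset[d]
    i[i < 1 | i > dm[d]] <- NA
    i
  })
  out <- do.call(`[`, c(list(a), idx))
  out[is.na(out)] <- fill
  array(out, dim = dm)
}

# logical mask of local maxima of |a| (strict, with plateau ties going to
# the lowest scan index)
local_max_mask <- function(a) {
  A <- abs(a)
  dm <- dim(A)
  strides <- cumprod(c(1, dm[-length(dm)]))
  offs <- as.matrix(expand.grid(rep(list(-1:1), length(dm))))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  mask <- array(TRUE, dim = dm)
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    nb <- shift_array(A, -o)              # value at p + o
    delta <- sum(o * strides)             # lin(p + o) - lin(p)
    ok <- if (delta > 0) A > nb | A == nb else A > nb
    mask <- mask & ok
  }
  mask
}

#' Pick local maxima above a contour level
#'
#' Returns every grid point whose absolute intensity is at least
#' \code{threshold} and beats all of its 3^N - 1 neighbors (plateau ties
#' resolve to the lowest scan index).  Positions are refined off-grid by
#' three-point parabolic interpolation per axis.
#'
#' @param spectrum an \code{\link{nmr_spectrum}}.
#' @param params a \code{\link{pick_params}} with \code{threshold > 0}.
#' @param refine parabolic sub-grid refinement (default TRUE).
#' @return an \code{\link{nmr_peaklist}} in scan order.
#' @export
pick_local_maxima <- function(spectrum, params, refine = TRUE) {
  stopifnot(params$threshold > 0)
  A <- abs(spectrum$data)
  mask <- local_max_mask(spectrum$data) & A >= params$threshold
  lin <- which(mask)                       # scan order
  if (!length(lin))
    return(nmr_peaklist(dimensionality = length(spectrum$axes),
                        source_spectrum = spectrum$name))
  idx <- arrayInd(lin, dim(A))
  peaks <- lapply(seq_along(lin), function(k) {
    i <- idx[k, ]
    fi <- as.numeric(i)
    if (refine) {
      for (d in seq_along(i)) {
        n <- dim(A)[d]
        if (i[d] > 1 && i[d] < n) {
          pick1 <- function(off) {
            j <- i; j[d] <- j[d] + off
            do.call(`[`, c(list(A), as.list(j)))
          }
          ym <- pick1(-1); y0 <- pick1(0); yp <- pick1(1)
          den <- ym - 2 * y0 + yp
          if (den < 0) fi[d] <- i[d] + min(0.5, max(-0.5,
                                                    0.5 * (ym - yp) / den))
        }
      }
    }
    nmr_peak(spectrum_ppm(spectrum, fi),
             height = do.call(`[`, c(list(spectrum$data), as.list(i))))
  })
  nmr_peaklist(peaks, length(spectrum$axes),
               source_spectrum = spectrum$name)
}

#' Restricted peak picking seeded by root peaks
#'
#' Picks local maxima of a 3D spectrum only inside the union of search
#' windows centered on 2D root peaks (e.g. HSQC amides): root position
#' +/- tolerance on the two shared axes, full range on the third.  Each
#' returned peak records the index of its (nearest) root.
#'
#' @param spectrum3d a 3D \code{\link{nmr_spectrum}}.
#' @param root_peaks a 2D \code{\link{nmr_peaklist}}.
#' @param params a \code{\link{pick_params}}.
#' @param root_nuclei nuclei of the two root dimensions, in root-peak
#'   dimension order (default \code{c("1H", "15N")}).
#' @param window explicit ppm half-widths for the two root dimensions;
#'   default taken from \code{params$tolerances} by nucleus class.
#' @return an \code{\link{nmr_peaklist}}; each peak's \code{root} field
#'   holds the root-peak index.
#' @export
restricted_pick <- function(spectrum3d, root_peaks, params,
                            root_nuclei = c("1H", "15N"), window = NULL) {
  if (length(spectrum3d$axes) != 3)
    stop("restricted_pick expects a 3D spectrum")
  if (root_peaks$dimensionality != 2)
    stop("root peak list must be 2D")
  nucs <- vapply(spectrum3d$axes, function(a) a$nucleus, character(1))
  axis_map <- match(root_nuclei, nucs)
  if (anyNA(axis_map) || axis_map[1] == axis_map[2])
    stop("no axis mapping found: spectrum axes (",
         paste(nucs, collapse = ", "), ") do not cover root nuclei (",
         paste(root_nuclei, collapse = ", "), ")")
  if (is.null(window))
    window <- vapply(root_nuclei, function(n) tol_for_nucleus(params, n),
                     numeric(1))
  picked <- pick_local_maxima(spectrum3d, params)
  if (!length(root_peaks$peaks) || !length(picked$peaks))
    return(nmr_peaklist(dimensionality = 3,
                        source_spectrum = spectrum3d$name))
  roots <- t(vapply(root_peaks$peaks, function(p) p$position, numeric(2)))
  keep <- list()
  for (p in picked$peaks) {
    dx <- abs(roots[, 1] - p$position[axis_map[1]]) / window[1]
    dy <- abs(roots[, 2] - p$position[axis_map[2]]) / window[2]
    inside <- dx <= 1 & dy <= 1
    if (any(inside)) {
      score <- ifelse(inside, dx^2 + dy^2, Inf)
      p$root <- which.min(score)
      keep[[length(keep) + 1]] <- p
    }
  }
  nmr_peaklist(keep, 3, source_spectrum = spectrum3d$name)
}

#' Sort peaks by absolute data height
#'
#' Descending \code{|height|}; ties keep their scan order (stable sort).
#'
#' @param peaklist an \code{\link{nmr_peaklist}}.
#' @return the sorted \code{\link{nmr_peaklist}}.
#' @export
sort_by_height <- function(peaklist) {
  h <- vapply(peaklist$peaks, function(p) abs(p$height), numeric(1))
  peaklist$peaks <- peaklist$peaks[order(-h)]
  peaklist
}

#' Re-center a peak on the nearest local maximum
#'
#' Moves the peak to the nearest local maximum within 2x tolerance per
#' axis, then clears the simulated flag and detaches the \code{"_s"}
#' suffix (the confirm step of predict-and-confirm).  When no maximum
#' lies inside the window the peak is returned unmoved, still flagged,
#' with a warning.
#'
#' @param spectrum the \code{\link{nmr_spectrum}} the peak lives on.
#' @param peak an \code{\link{nmr_peak}}.
#' @param params a \code{\link{pick_params}} (tolerances only).
#' @return the centered \code{\link{nmr_peak}}.
#' @export
center_peak <- function(spectrum, peak, params = pick_params()) {
  nd <- length(spectrum$axes)
  stopifnot(length(peak$position) == nd)
  tol <- vapply(spectrum$axes, function(a)
    tol_for_nucleus(params, a$nucleus), numeric(1))
  mask <- local_max_mask(spectrum$data)
  lin <- which(mask)
  ok <- rep(TRUE, length(lin))
  idx <- arrayInd(lin, dim(spectrum$data))
  score <- rep(0, length(lin))
  for (d in seq_len(nd)) {
    ppm_d <- axis_ppm(spectrum$axes[[d]], idx[, d])
    rel <- abs(ppm_d - peak$position[d]) / (2 * tol[d])
    ok <- ok & rel <= 1
    score <- score + rel^2
  }
  if (!any(ok)) {
    warning("no local maximum within the search window; peak not moved")
    return(peak)
  }
  best <- idx[which(ok)[which.min(score[ok])], ]
  fi <- as.numeric(best)
  A <- abs(spectrum$data)
  for (d in seq_len(nd)) {
    n <- dim(A)[d]
    if (best[d] > 1 && best[d] < n) {
      pick1 <- function(off) {
        j <- best; j[d] <- j[d] + off
        do.call(`[`, c(list(A), as.list(j)))
      }
      den <- pick1(-1) - 2 * pick1(0) + pick1(1)
      if (den < 0)
        fi[d] <- best[d] + min(0.5, max(-0.5,
                                        0.5 * (pick1(-1) - pick1(1)) / den))
    }
  }
  peak$position <- spectrum_ppm(spectrum, fi)
  peak$height <- do.call(`[`, c(list(spectrum$data), as.list(best)))
  peak$flags <- setdiff(peak$flags, "simulated")
  peak$assignment <- sub("_s$", "", peak$assignment)
  peak
}
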