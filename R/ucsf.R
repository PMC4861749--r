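#' Read a Sparky UCSF spectrum
#'
#' Reads the canonical UCSF layout: 10-byte magic \code{"UCSF NMR"},
#' dimension byte at offset 10, single real component, format version 2,
#' one 128-byte header per axis, then big-endian 32-bit float data stored
#' in tiles with the last axis fastest.  Anything else is rejected rather
#' than guessed.
#'
#' @param path file path.
#' @return an \code{\link{nmr_spectrum}} with dense (untiled) data.  Axis 1
#'   of the returned spectrum is the file's w1 (slowest-varying) axis.
#' @export
read_ucsf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 10)
  if (!identical(rawToChar(magic[1:8]), "UCSF NMR"))
    stop("not a UCSF file: bad magic in ", path)
  ndim <- as.integer(readBin(con, "raw", 1))
  ncomp <- as.integer(readBin(con, "raw", 1))
  readBin(con, "raw", 1)                       # unused
  version <- as.integer(readBin(con, "raw", 1))
  if (ndim < 2 || ndim > 4)
    stop("unsupported UCSF dimensionality: ", ndim)
  if (ncomp != 1)
    stop("unsupported UCSF component count: ", ncomp)
  readBin(con, "raw", 180 - 14)                # header padding
  axes <- vector("list", ndim)
  np <- integer(ndim); tile <- integer(ndim)
  for (d in seq_len(ndim)) {
    blk <- readBin(con, "raw", 128)
    nb <- blk[1:6]
    nb <- nb[cumsum(nb == as.raw(0)) == 0]
    nuc <- trimws(rawToChar(nb))
    np[d] <- readBin(blk[9:12], "integer", 1, size = 4, endian = "big")
    tile[d] <- readBin(blk[17:20], "integer", 1, size = 4, endian = "big")
    sf <- readBin(blk[21:24], "numeric", 1, size = 4, endian = "big")
    sw <- readBin(blk[25:28], "numeric", 1, size = 4, endian = "big")
    ce <- readBin(blk[29:32], "numeric", 1, size = 4, endian = "big")
    axes[[d]] <- nmr_axis(nuc, np[d], sw, sf, ce)
  }
  ntile <- ceiling(np / tile)
  total <- prod(ntile * tile)
  vals <- readBin(con, "numeric", total, size = 4, endian = "big")
  if (length(vals) < total)
    stop("truncated UCSF data section in ", path)
  out <- array(0, dim = np)
  tlen <- prod(tile)
  # tiles and in-tile elements are row-major: last axis fastest
  tgrid <- as.matrix(rev(expand.grid(rev(lapply(ntile, seq_len)))))
  for (k in seq_len(nrow(tgrid))) {
    block <- vals[((k - 1) * tlen + 1):(k * tlen)]
    ta <- aperm(array(block, dim = rev(tile)), rev(seq_len(ndim)))
    src <- dst <- vector("list", ndim)
    for (d in seq_len(ndim)) {
      lo <- (tgrid[k, d] - 1L) * tile[d] + 1L
      hi <- min(lo + tile[d] - 1L, np[d])
      dst[[d]] <- lo:hi
      src[[d]] <- seq_len(hi - lo + 1L)
    }
    out <- do.call(`[<-`, c(list(out), dst,
                            list(do.call(`[`, c(list(ta), src,
                                                list(drop = FALSE))))))
  }
  sp <- nmr_spectrum(axes, out,
                     name = sub("\\.ucsf$", "", basename(path)))
  sp
}

#' Write a Sparky UCSF spectrum
#'
#' Inverse of \code{\link{read_ucsf}}.  Data are written big-endian 32-bit
#' float in the canonical tiled layout.
#'
#' @param spectrum an \code{\link{nmr_spectrum}} (2 to 4 dimensions).
#' @param path output path.
#' @param tile integer tile edge per axis; default one tile spanning each
#'   whole axis.
#' @return \code{path}, invisibly.
#' @export
write_ucsf <- function(spectrum, path, tile = NULL) {
  ndim <- length(spectrum$axes)
  if (ndim < 2 || ndim > 4)
    stop("unsupported dimensionality for UCSF: ", ndim)
  np <- vapply(spectrum$axes, function(a) a$n_points, integer(1))
  if (is.null(tile)) tile <- np
  tile <- as.integer(rep_len(tile, ndim))
  stopifnot(all(tile >= 1))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("UCSF NMR"), as.raw(c(0, 0))), con)
  writeBin(as.raw(c(ndim, 1, 0, 2)), con)
  writeBin(raw(180 - 14), con)
  for (d in seq_len(ndim)) {
    ax <- spectrum$axes[[d]]
    nuc <- charToRaw(ax$nucleus)
    blk <- raw(128)
    blk[seq_along(nuc[1:min(6, length(nuc))])] <- nuc[1:min(6, length(nuc))]
    blk[9:12] <- writeBin(np[d], raw(), size = 4, endian = "big")
    blk[17:20] <- writeBin(tile[d], raw(), size = 4, endian = "big")
    blk[21:24] <- writeBin(ax$spectrometer_freq, raw(), size = 4,
                           endian = "big")
    blk[25:28] <- writeBin(ax$spectral_width, raw(), size = 4,
                           endian = "big")
    blk[29:32] <- writeBin(ax$center_ppm, raw(), size = 4, endian = "big")
    writeBin(blk, con)
  }
  ntile <- ceiling(np / tile)
  tgrid <- as.matrix(rev(expand.grid(rev(lapply(ntile, seq_len)))))
  for (k in seq_len(nrow(tgrid))) {
    ta <- array(0, dim = tile)
    src <- dst <- vector("list", ndim)
    for (d in seq_len(ndim)) {
      lo <- (tgrid[k, d] - 1L) * tile[d] + 1L
      hi <- min(lo + tile[d] - 1L, np[d])
      src[[d]] <- lo:hi
      dst[[d]] <- seq_len(hi - lo + 1L)
    }
    ta <- do.call(`[<-`, c(list(ta), dst,
                           list(do.call(`[`, c(list(spectrum$data), src,
                                               list(drop = FALSE))))))
    # row-major serialization: reverse dims then flatten column-major
    writeBin(as.vector(aperm(ta, rev(seq_len(ndim)))), con,
             size = 4, endian = "big")
  }
  invisible(path)
}
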