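#' Flag peaks that are not part of spin systems as noise
#'
#' Root coordinates (by default dimensions 1-2 of every list, typically
#' HN/N) are clustered across spectra; peaks whose cluster is supported by
#' at least \code{min_spectra_support} distinct spectra are kept, all
#' others receive the \code{"noise"} flag.  Flagging is non-destructive:
#' deletion is a separate, explicit step
#' (\code{\link{drop_flagged_peaks}}).
#'
#' @param peaklists list of at least two \code{\link{nmr_peaklist}}s
#'   sharing the root dimensions.
#' @param params a \code{\link{pick_params}} (uses
#'   \code{min_spectra_support}).
#' @param root_dims the two shared dimensions (default \code{c(1, 2)}).
#' @param root_tol ppm tolerance per root dimension (default H/N
#'   tolerances from \code{params}).
#' @return list with \code{peaklists} (flags updated) and \code{index}, a
#'   data.frame of clusters (centroids, member count, spectra support,
#'   kept flag).
#' @export
flag_noise_by_spin_system <- function(peaklists, params = pick_params(),
                                      root_dims = c(1, 2),
                                      root_tol = NULL) {
  if (length(peaklists) < 2)
    stop("need at least two peak lists to cross-validate spin systems")
  if (is.null(root_tol))
    root_tol <- unname(params$tolerances[c("H", "N")])
  pts <- do.call(rbind, lapply(seq_along(peaklists), function(s) {
    pl <- peaklists[[s]]
    if (!length(pl$peaks)) return(NULL)
    cbind(spectrum = s, peak = seq_along(pl$peaks),
          t(vapply(pl$peaks, function(p) p$position[root_dims],
                   numeric(2))))
  }))
  centers <- matrix(numeric(), 0, 2)
  members <- list()
  for (r in seq_len(NROW(pts))) {
    xy <- pts[r, 3:4]
    hit <- which(abs(centers[, 1] - xy[1]) <= root_tol[1] &
                 abs(centers[, 2] - xy[2]) <= root_tol[2])
    if (length(hit)) {
      k <- hit[1]
      members[[k]] <- c(members[[k]], r)
      centers[k, ] <- colMeans(pts[members[[k]], 3:4, drop = FALSE])
    } else {
      centers <- rbind(centers, xy)
      members[[nrow(centers)]] <- r
    }
  }
  support <- vapply(members, function(m)
    length(unique(pts[m, 1])), integer(1))
  kept <- support >= params$min_spectra_support
  for (k in seq_along(members)) {
    if (kept[k]) next
    for (r in members[[k]]) {
      s <- pts[r, 1]; i <- pts[r, 2]
      fl <- peaklists[[s]]$peaks[[i]]$flags
      peaklists[[s]]$peaks[[i]]$flags <- union(fl, "noise")
    }
  }
  index <- data.frame(cluster = seq_along(members),
                      w1 = centers[, 1], w2 = centers[, 2],
                      n_peaks = lengths(members),
                      n_spectra = support, kept = kept)
  list(peaklists = peaklists, index = index)
}

#' Delete flagged peaks from a peak list
#'
#' @param peaklist an \code{\link{nmr_peaklist}}.
#' @param flag flag to drop on (default \code{"noise"}).
#' @return the filtered \code{\link{nmr_peaklist}}.
#' @export
drop_flagged_peaks <- function(peaklist, flag = "noise") {
  peaklist$peaks <- Filter(function(p) !flag %in% p$flags,
                           peaklist$peaks)
  peaklist
}
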