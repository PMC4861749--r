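#' Spectral-series table
#'
#' Observable values (shift in ppm, or peak height) for residues across a
#' series of conditions (molar ratio, time, pH...).  Conditions are kept
#' strictly increasing; missing cells are explicit \code{NA}s.
#'
#' @param conditions numeric condition values (any order; sorted on
#'   construction; must be distinct).
#' @param values numeric matrix, residues x conditions; rownames are
#'   residue indices.
#' @param observable label, e.g. \code{"height"} or \code{"shift_H"}.
#' @param condition_name label, e.g. \code{"time_s"} or
#'   \code{"molar_ratio"}.
#' @return an object of class \code{series_table}.
#' @export
series_table <- function(conditions, values, observable = "height",
                         condition_name = "condition") {
  values <- as.matrix(values)
  stopifnot(length(conditions) == ncol(values))
  if (anyDuplicated(conditions)) stop("condition values must be distinct")
  o <- order(conditions)
  structure(list(conditions = as.numeric(conditions)[o],
                 values = values[, o, drop = FALSE],
                 observable = observable,
                 condition_name = condition_name),
            class = "series_table")
}

#' @export
print.series_table <- function(x, ...) {
  cat(sprintf("<series_table> %s over %d %s points, %d residues\n",
              x$observable, length(x$conditions), x$condition_name,
              nrow(x$values)))
  invisible(x)
}

# residue index parsed from a Sparky label like "A5HN" -> 5
.label_residue <- function(label) {
  m <- regmatches(label, regexec("^[A-Za-z]([0-9]+)", label))[[1]]
  if (length(m) == 2) as.integer(m[2]) else NA_integer_
}

# per-residue dim shifts of an assigned 2D peak list
peaklist_residue_shifts <- function(peaklist) {
  rows <- lapply(peaklist$peaks, function(p) {
    r <- .label_residue(p$assignment[1])
    if (is.na(r)) return(NULL)
    c(residue = r, p$position)
  })
  rows <- do.call(rbind, Filter(Negate(is.null), rows))
  df <- as.data.frame(rows)
  names(df) <- c("residue", paste0("w", seq_len(peaklist$dimensionality)))
  df[!duplicated(df$residue), , drop = FALSE]
}

#' Chemical-shift perturbation between two conditions
#'
#' Compares two assigned peak lists recorded under different conditions.
#' \code{single_nucleus} returns the signed shift difference (b - a) of
#' the chosen dimension; \code{composite} returns
#' \code{sqrt(dH^2 + (w * dX)^2)} with the heteronucleus scaling
#' \code{w} (defaults: 0.14 for 15N, 0.25 for 13C).  Residues present in
#' only one list are reported as missing, never as zero.
#'
#' @param list_a,list_b assigned 2D \code{\link{nmr_peaklist}}s
#'   (dimension 1 = 1H, dimension 2 = heteronucleus).
#' @param mode \code{"composite"} or \code{"single_nucleus"}.
#' @param weights heteronucleus scaling per class.
#' @param nucleus_dim dimension used in \code{single_nucleus} mode
#'   (default 1, the amide proton).
#' @param heteronucleus_class \code{"N"} or \code{"C"}: which weight
#'   applies to dimension 2 in composite mode.
#' @return data.frame with \code{residue}, \code{delta} and
#'   \code{missing} columns (delta is \code{NA} where missing).
#' @export
perturbation <- function(list_a, list_b,
                         mode = c("composite", "single_nucleus"),
                         weights = c(N = 0.14, C = 0.25),
                         nucleus_dim = 1, heteronucleus_class = "N") {
  mode <- match.arg(mode)
  a <- peaklist_residue_shifts(list_a)
  b <- peaklist_residue_shifts(list_b)
  res <- sort(union(a$residue, b$residue))
  out <- data.frame(residue = res, delta = NA_real_, missing = FALSE)
  for (k in seq_along(res)) {
    ia <- match(res[k], a$residue); ib <- match(res[k], b$residue)
    if (is.na(ia) || is.na(ib)) { out$missing[k] <- TRUE; next }
    if (mode == "single_nucleus") {
      cn <- paste0("w", nucleus_dim)
      out$delta[k] <- b[[cn]][ib] - a[[cn]][ia]
    } else {
      dh <- b$w1[ib] - a$w1[ia]
      dx <- b$w2[ib] - a$w2[ia]
      w <- unname(weights[heteronucleus_class])
      out$delta[k] <- sqrt(dh^2 + (w * dx)^2)
    }
  }
  out
}

#' Trace one resonance across a spectral series
#'
#' @param series a \code{\link{series_table}}.
#' @param residue residue index (must be a row of the series).
#' @return data.frame \code{(condition, value)} ordered by condition;
#'   missing points are kept as \code{NA} rows (gaps preserved).
#' @export
titration_trace <- function(series, residue) {
  i <- match(as.character(residue), rownames(series$values))
  if (is.na(i)) stop("residue ", residue, " not in series")
  data.frame(condition = series$conditions,
             value = as.numeric(series$values[i, ]))
}

#' Fit a mono-exponential decay to time/height pairs
#'
#' Least-squares fit of \code{I(t) = I0 * exp(-R * t)} (optionally plus a
#' constant offset), initialized from a log-linear regression and refined
#' by Levenberg-Marquardt with \code{I0 > 0}, \code{R >= 0}.
#'
#' @param time numeric times (s).
#' @param heights positive peak heights.
#' @param offset include a constant offset term (default FALSE).
#' @return an object of class \code{decay_fit}: \code{I0}, \code{R}
#'   (1/s), \code{T = 1/R} (s), \code{rms} residual, \code{offset}.
#' @export
fit_exponential_decay <- function(time, heights, offset = FALSE) {
  ok <- is.finite(time) & is.finite(heights)
  time <- time[ok]; heights <- heights[ok]
  if (length(time) < 3)
    stop("decay fit refused: need at least 3 finite points, got ",
         length(time))
  if (any(heights <= 0))
    stop("decay fit refused: non-positive heights present")
  lf <- stats::lm(log(heights) ~ time)
  i0 <- exp(unname(stats::coef(lf)[1]))
  r0 <- max(0, -unname(stats::coef(lf)[2]))
  if (r0 < 1e-10) r0 <- 0          # flat data: keep the start on the bound
  df <- data.frame(t = time, I = heights)
  # degenerate flat data defeats the LM gradient check; the log-linear
  # solution already is the least-squares optimum there
  if (!offset && r0 == 0 &&
      max(abs(heights - mean(heights))) < 1e-9 * mean(heights)) {
    i0 <- mean(heights)
    return(structure(list(I0 = i0, R = 0, T = Inf, offset = 0,
                          rms = sqrt(mean((heights - i0)^2)),
                          n = length(time)),
                     class = "decay_fit"))
  }
  fit <- if (offset) {
    minpack.lm::nlsLM(I ~ I0 * exp(-R * t) + C, data = df,
                      start = list(I0 = i0, R = r0, C = 0),
                      lower = c(1e-12, 0, -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    minpack.lm::nlsLM(I ~ I0 * exp(-R * t), data = df,
                      start = list(I0 = i0, R = r0),
                      lower = c(1e-12, 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  cf <- stats::coef(fit)
  structure(list(I0 = unname(cf["I0"]), R = unname(cf["R"]),
                 T = if (cf["R"] > 0) unname(1 / cf["R"]) else Inf,
                 offset = if (offset) unname(cf["C"]) else 0,
                 rms = sqrt(mean(stats::residuals(fit)^2)),
                 n = length(time)),
            class = "decay_fit")
}

#' Fit the relaxation decay of one residue in a series
#'
#' @param series a \code{\link{series_table}} whose conditions are times.
#' @param residue residue index.
#' @param offset include a constant offset term.
#' @return a \code{decay_fit}; see \code{\link{fit_exponential_decay}}.
#' @export
fit_decay <- function(series, residue, offset = FALSE) {
  tr <- titration_trace(series, residue)
  fit_exponential_decay(tr$condition, tr$value, offset = offset)
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> I0 = %.4g, R = %.4g /s (T = %.4g s), rms %.3g\n",
              x$I0, x$R, x$T, x$rms))
  invisible(x)
}

#' Read / write a series table as TSV
#'
#' Layout: first column \code{residue}, one column per condition named by
#' its numeric value; the observable and condition names travel in a
#' leading comment line.
#'
#' @param path file path.
#' @return \code{read_series_tsv}: a \code{\link{series_table}}.
#' @export
read_series_tsv <- function(path) {
  first <- readLines(path, n = 1)
  meta <- strsplit(sub("^# ", "", first), "\t")[[1]]
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df$residue
  series_table(as.numeric(colnames(v)), v,
               observable = meta[1], condition_name = meta[2])
}

#' @rdname read_series_tsv
#' @param series a \code{\link{series_table}}.
#' @export
write_series_tsv <- function(series, path) {
  lines <- c(sprintf("# %s\t%s", series$observable, series$condition_name),
             paste(c("residue", format(series$conditions)),
                   collapse = "\t"))
  for (r in seq_len(nrow(series$values)))
    lines <- c(lines, paste(c(rownames(series$values)[r],
                              format(series$values[r, ], digits = 10)),
                            collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Per-residue and per-spectrum height summaries
#'
#' @param series a \code{\link{series_table}} of heights.
#' @return list of data.frames: \code{per_residue} (mean/min/max across
#'   spectra) and \code{per_spectrum} (condition, total height).
#' @export
height_profiles <- function(series) {
  v <- series$values
  per_residue <- data.frame(residue = as.integer(rownames(v)),
                            mean = apply(v, 1, mean, na.rm = TRUE),
                            min = apply(v, 1, min, na.rm = TRUE),
                            max = apply(v, 1, max, na.rm = TRUE),
                            row.names = NULL)
  per_spectrum <- data.frame(condition = series$conditions,
                             total = colSums(v, na.rm = TRUE),
                             row.names = NULL)
  list(per_residue = per_residue, per_spectrum = per_spectrum)
}
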