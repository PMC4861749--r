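#' Residue-pair weight matrix (blacklist/whitelist)
#'
#' Symmetric per-residue-pair weighting used to steer NOE assignment:
#' \code{demoted} pairs (blacklist) are removed from candidate sets,
#' \code{promoted} pairs (whitelist) win ties.  Default everywhere is
#' \code{normal}.
#'
#' @param n_residues sequence length.
#' @return an object of class \code{pair_weights}.
#' @export
pair_weights <- function(n_residues) {
  stopifnot(n_residues >= 1)
  structure(list(n = as.integer(n_residues),
                 entries = data.frame(i = integer(), j = integer(),
                                      weight = character(),
                                      stringsAsFactors = FALSE)),
            class = "pair_weights")
}

#' Query a pair weight
#'
#' @param matrix a \code{\link{pair_weights}}.
#' @param residue_i,residue_j residue indices (order-free).
#' @return \code{"normal"}, \code{"promoted"} or \code{"demoted"}.
#' @export
pair_weight <- function(matrix, residue_i, residue_j) {
  if (residue_i < 1 || residue_i > matrix$n ||
      residue_j < 1 || residue_j > matrix$n)
    stop("residue pair (", residue_i, ", ", residue_j,
         ") outside the sequence")
  lo <- min(residue_i, residue_j); hi <- max(residue_i, residue_j)
  k <- which(matrix$entries$i == lo & matrix$entries$j == hi)
  if (length(k)) matrix$entries$weight[k] else "normal"
}

#' Promote, demote or reset a residue pair
#'
#' Updates are symmetric and last-write-wins.
#'
#' @param matrix a \code{\link{pair_weights}}.
#' @param residue_i,residue_j residue indices.
#' @param action \code{"promote"}, \code{"demote"} or \code{"normal"}.
#' @return the updated \code{\link{pair_weights}}.
#' @export
edit_pair_weights <- function(matrix, residue_i, residue_j,
                              action = c("promote", "demote", "normal")) {
  action <- match.arg(action)
  pair_weight(matrix, residue_i, residue_j)   # bounds check
  lo <- min(residue_i, residue_j); hi <- max(residue_i, residue_j)
  k <- which(matrix$entries$i == lo & matrix$entries$j == hi)
  if (length(k)) matrix$entries <- matrix$entries[-k, , drop = FALSE]
  if (action != "normal")
    matrix$entries <- rbind(matrix$entries,
                            data.frame(i = lo, j = hi,
                                       weight = paste0(action, "d"),
                                       stringsAsFactors = FALSE))
  matrix
}

#' Write pair weights as TSV
#'
#' @param matrix a \code{\link{pair_weights}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_pair_weights <- function(matrix, path) {
  df <- matrix$entries
  df <- df[order(df$i, df$j), , drop = FALSE]
  lines <- c(sprintf("# n_residues=%d", matrix$n), "i\tj\tweight",
             sprintf("%d\t%d\t%s", df$i, df$j, df$weight))
  writeLines(lines, path)
  invisible(path)
}

#' Read pair weights from TSV
#'
#' @param path input path (as written by \code{\link{write_pair_weights}}).
#' @return a \code{\link{pair_weights}}.
#' @export
read_pair_weights <- function(path) {
  first <- readLines(path, n = 1)
  n <- as.integer(sub("# n_residues=", "", first, fixed = TRUE))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  m <- pair_weights(n)
  if (nrow(df)) m$entries <- df[, c("i", "j", "weight")]
  m
}
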