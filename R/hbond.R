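.angle_deg <- function(v1, v2) {
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Detect backbone hydrogen bonds in a structure ensemble
#'
#' A donor amide (N, HN) and acceptor carbonyl O form a hydrogen bond
#' when H...O < 2.5 Angstrom, N...O < 3.5 Angstrom and the N-H...O angle
#' exceeds 120 degrees in at least the stated fraction of models
#' (default one half).
#'
#' @param ensemble an \code{\link{nmr_ensemble}} with backbone N, HN and
#'   O atoms.
#' @param criteria list overriding \code{h_o_max} (2.5), \code{n_o_max}
#'   (3.5), \code{angle_min} (120) and \code{min_fraction} (0.5).
#' @return data.frame of class \code{hbond_table}: donor/acceptor
#'   residues and types, mean geometry over satisfying models, fraction
#'   of models, origin.
#' @export
detect_hbonds <- function(ensemble, criteria = list()) {
  cr <- utils::modifyList(list(h_o_max = 2.5, n_o_max = 3.5,
                               angle_min = 120, min_fraction = 0.5),
                          criteria)
  res <- as.integer(names(ensemble$sequence))
  rows <- list()
  don <- list(); acc <- list()
  for (r in res) {
    ni <- atom_row(ensemble, r, "N"); hi <- atom_row(ensemble, r, "HN")
    oi <- atom_row(ensemble, r, "O")
    if (length(ni) && length(hi)) don[[as.character(r)]] <- c(ni, hi)
    if (length(oi)) acc[[as.character(r)]] <- oi
  }
  missing_bb <- setdiff(as.character(res), union(names(don), names(acc)))
  for (r in missing_bb)
    warning("residue ", r, ": backbone atoms missing, skipped")
  nm <- ensemble$n_models
  for (dr in names(don)) for (ar in names(acc)) {
    if (dr == ar) next
    ok <- logical(nm); ho <- no <- ang <- numeric(nm)
    for (m in seq_len(nm)) {
      xyz <- model_xyz(ensemble, m)
      N <- xyz[don[[dr]][1], ]; H <- xyz[don[[dr]][2], ]
      O <- xyz[acc[[ar]], ]
      ho[m] <- sqrt(sum((H - O)^2))
      no[m] <- sqrt(sum((N - O)^2))
      ang[m] <- .angle_deg(N - H, O - H)
      ok[m] <- ho[m] < cr$h_o_max && no[m] < cr$n_o_max &&
        ang[m] > cr$angle_min
    }
    if (mean(ok) >= cr$min_fraction) {
      rows[[length(rows) + 1]] <- data.frame(
        donor_res = as.integer(dr),
        donor_type = unname(ensemble$sequence[dr]),
        acceptor_res = as.integer(ar),
        acceptor_type = unname(ensemble$sequence[ar]),
        h_o = mean(ho[ok]), n_o = mean(no[ok]), angle = mean(ang[ok]),
        fraction = mean(ok), origin = "model_distance",
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(donor_res = integer(), donor_type = character(),
               acceptor_res = integer(), acceptor_type = character(),
               h_o = numeric(), n_o = numeric(), angle = numeric(),
               fraction = numeric(), origin = character(),
               stringsAsFactors = FALSE)
  class(out) <- c("hbond_table", "data.frame")
  out
}

#' Convert hydrogen bonds to distance constraints
#'
#' Each hydrogen bond yields two constraints: HN-O with bounds
#' 1.8-2.3 Angstrom and N-O with bounds 2.8-3.3 Angstrom.
#'
#' @param hbonds a \code{\link{detect_hbonds}} result.
#' @return a \code{\link{constraint_table}} with source \code{"hbond"}.
#' @export
hbond_constraints <- function(hbonds) {
  if (!nrow(hbonds)) return(empty_constraints())
  constraint_table(
    res_i = rep(hbonds$donor_res, each = 2),
    atom_i = rep(c("HN", "N"), nrow(hbonds)),
    res_j = rep(hbonds$acceptor_res, each = 2),
    atom_j = "O",
    upper = rep(c(2.3, 3.3), nrow(hbonds)),
    lower = rep(c(1.8, 2.8), nrow(hbonds)),
    res_type_i = rep(hbonds$donor_type, each = 2),
    res_type_j = rep(hbonds$acceptor_type, each = 2),
    source = "hbond")
}
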