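# shared fixtures and independent oracles; header values are chosen
# binary-exact so float32 spectrum headers round-trip exactly

ax_h <- function(n = 64) nmr_axis("1H", n, 4096, 512, 6)    # 2-10 ppm
ax_n <- function(n = 64) nmr_axis("15N", n, 2048, 64, 118)  # 102-134 ppm
ax_c <- function(n = 64) nmr_axis("13C", n, 4096, 128, 44)  # 28-60 ppm

# exhaustive local-maximum oracle: |I| >= threshold and beats every
# neighbor, equal neighbors only allowed at higher linear index
brute_force_maxima <- function(data, threshold) {
  A <- abs(data)
  dm <- dim(A)
  nd <- length(dm)
  offs <- as.matrix(expand.grid(rep(list(-1:1), nd)))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  strides <- cumprod(c(1, dm[-nd]))
  hits <- integer()
  for (lin in seq_along(A)) {
    if (A[lin] < threshold) next
    p <- arrayInd(lin, dm)
    is_max <- TRUE
    for (r in seq_len(nrow(offs))) {
      q <- p + offs[r, ]
      if (any(q < 1 | q > dm)) next
      qlin <- 1 + sum((q - 1) * strides)
      if (A[qlin] > A[lin] || (A[qlin] == A[lin] && qlin < lin)) {
        is_max <- FALSE
        break
      }
    }
    if (is_max) hits <- c(hits, lin)
  }
  arrayInd(hits, dm)
}

# grid indices of a picked peak list (nearest grid point per axis)
peak_grid_indices <- function(peaklist, spectrum) {
  t(vapply(peaklist$peaks, function(p)
    vapply(seq_along(spectrum$axes), function(d)
      axis_index(spectrum$axes[[d]], p$position[d]), integer(1)),
    integer(length(spectrum$axes))))
}

# small assigned 2D peak list from residue/shift vectors
hsqc_list <- function(residues, h, n, types = "ALA") {
  types <- rep_len(types, length(residues))
  peaks <- lapply(seq_along(residues), function(i)
    nmr_peak(c(h[i], n[i]), height = 1,
             assignment = c(sprintf("A%dHN", residues[i]),
                            sprintf("A%dN", residues[i]))))
  nmr_peaklist(peaks, 2)
}

# tiny two-atom ensemble with two protons a fixed distance apart
two_proton_ensemble <- function(d) {
  atoms <- data.frame(residue_index = c(1, 5),
                      residue_type = "ALA",
                      atom_name = "HA", element = "H",
                      stringsAsFactors = FALSE)
  nmr_ensemble(atoms, array(c(0, d, 0, 0, 0, 0), c(2, 3, 1)))
}
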