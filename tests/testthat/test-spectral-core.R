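test_that("axis index/ppm conversion is a monotonic bijection on the grid", {
  for (ax in list(ax_h(33), ax_n(64), ax_c(17))) {
    ppm <- axis_ppm(ax, seq_len(ax$n_points))
    expect_true(all(diff(ppm) < 0))            # downfield first
    expect_equal(axis_index(ax, ppm), seq_len(ax$n_points))
    # off-grid ppm snaps to the nearest grid point (within half a step)
    expect_equal(axis_index(ax, ppm + 0.49 * axis_step(ax)),
                 seq_len(ax$n_points))
  }
})

test_that("UCSF files round-trip, including zero grids", {
  sp <- nmr_spectrum(list(ax_h(8), ax_n(6)), array(0, c(8, 6)), "zeros")
  f <- withr::local_tempfile(fileext = ".ucsf")
  write_ucsf(sp, f)
  back <- read_ucsf(f)
  expect_identical(dim(back$data), c(8L, 6L))
  expect_true(all(back$data == 0))

  set.seed(41)
  for (dims in list(c(16, 12), c(8, 6, 10), c(4, 5, 3, 6))) {
    axes <- list(ax_h(dims[1]), ax_n(dims[2]), ax_c(64),
                 ax_h(64))[seq_along(dims)]
    axes <- lapply(seq_along(dims), function(d) {
      a <- axes[[d]]; a$n_points <- as.integer(dims[d]); a
    })
    # float32-exact values so the header round-trips bit-for-bit
    data <- array(round(rnorm(prod(dims)), 3), dim = dims)
    sp <- nmr_spectrum(axes, data, "rt")
    f2 <- withr::local_tempfile(fileext = ".ucsf")
    write_ucsf(sp, f2, tile = pmin(dims, 5))
    back <- read_ucsf(f2)
    expect_equal(back$data, sp$data, tolerance = 1e-6)
    for (d in seq_along(dims)) {
      expect_identical(back$axes[[d]]$nucleus, sp$axes[[d]]$nucleus)
      expect_equal(axis_ppm(back$axes[[d]], seq_len(dims[d])),
                   axis_ppm(sp$axes[[d]], seq_len(dims[d])),
                   tolerance = 1e-9)
    }
  }
})

test_that("tiled UCSF layout matches an independent offset calculation", {
  # oracle: write the file directly, computing every tile/element offset
  # from first principles (row-major tiles, last axis fastest, padding)
  np <- c(5L, 7L, 4L); tile <- c(2L, 3L, 4L)
  ntile <- as.integer(ceiling(np / tile))
  set.seed(7)
  vals <- array(rnorm(prod(np)), dim = np)
  f <- withr::local_tempfile(fileext = ".ucsf")
  con <- file(f, "wb")
  writeBin(c(charToRaw("UCSF NMR"), as.raw(c(0, 0))), con)
  writeBin(as.raw(c(3, 1, 0, 2)), con)
  writeBin(raw(180 - 14), con)
  nucs <- c("1H", "15N", "13C")
  for (d in 1:3) {
    blk <- raw(128)
    nb <- charToRaw(nucs[d])
    blk[seq_along(nb)] <- nb
    blk[9:12] <- writeBin(np[d], raw(), size = 4, endian = "big")
    blk[17:20] <- writeBin(tile[d], raw(), size = 4, endian = "big")
    blk[21:24] <- writeBin(512, raw(), size = 4, endian = "big")
    blk[25:28] <- writeBin(2048, raw(), size = 4, endian = "big")
    blk[29:32] <- writeBin(40, raw(), size = 4, endian = "big")
    writeBin(blk, con)
  }
  buf <- numeric(prod(ntile) * prod(tile))
  for (i in seq_len(np[1])) for (j in seq_len(np[2]))
    for (k in seq_len(np[3])) {
      ti <- (i - 1) %/% tile[1]; tj <- (j - 1) %/% tile[2]
      tk <- (k - 1) %/% tile[3]
      li <- (i - 1) %% tile[1]; lj <- (j - 1) %% tile[2]
      lk <- (k - 1) %% tile[3]
      tile_no <- (ti * ntile[2] + tj) * ntile[3] + tk
      elem <- (li * tile[2] + lj) * tile[3] + lk
      buf[tile_no * prod(tile) + elem + 1] <- vals[i, j, k]
    }
  writeBin(buf, con, size = 4, endian = "big")
  close(con)
  back <- read_ucsf(f)
  set.seed(8)
  for (r in 1:10) {
    idx <- c(sample(np[1], 1), sample(np[2], 1), sample(np[3], 1))
    expect_equal(back$data[idx[1], idx[2], idx[3]],
                 vals[idx[1], idx[2], idx[3]], tolerance = 1e-6)
  }
})

test_that("read_ucsf rejects bad magic and unsupported layouts", {
  f <- withr::local_tempfile()
  writeBin(charToRaw("NOTUCSF..."), f)
  expect_error(read_ucsf(f), "magic")
  sp <- nmr_spectrum(list(ax_h(4), ax_n(4)), array(0, c(4, 4)))
  f2 <- withr::local_tempfile(fileext = ".ucsf")
  write_ucsf(sp, f2)
  raw <- readBin(f2, "raw", file.size(f2))
  raw[12] <- as.raw(3)                          # claim 3 components
  writeBin(raw, f2)
  expect_error(read_ucsf(f2), "component")
})

test_that("Sparky peak lists parse and round-trip", {
  f <- withr::local_tempfile(fileext = ".list")
  writeLines(c("Assignment\tw1\tw2\tData Height",
               "A5HN-A5N 8.12 119.3 1.2e6",
               "G7HN-N 8.40 108.2 5.5e5",
               "?-? 7.77 115.0 2.0e4"), f)
  pl <- read_peaklist(f)
  expect_equal(length(pl$peaks), 3)
  expect_equal(pl$peaks[[1]]$assignment, c("A5HN", "A5N"))
  expect_equal(pl$peaks[[1]]$position, c(8.12, 119.3))
  expect_equal(pl$peaks[[1]]$height, 1.2e6)
  expect_equal(pl$peaks[[2]]$assignment, c("G7HN", "G7N"))  # carried residue
  expect_true(all(is.na(pl$peaks[[3]]$assignment)))
  for (dialect in c("sparky_list", "tsv")) {
    f2 <- withr::local_tempfile()
    write_peaklist(pl, f2, dialect)
    back <- read_peaklist(f2, dialect)
    expect_equal(length(back$peaks), 3)
    for (i in 1:3) {
      expect_equal(back$peaks[[i]]$position, pl$peaks[[i]]$position,
                   tolerance = 1e-4)
      expect_equal(back$peaks[[i]]$assignment, pl$peaks[[i]]$assignment)
    }
  }
  # empty file -> empty list; malformed line -> error with line number
  f3 <- withr::local_tempfile(); writeLines(character(), f3)
  expect_equal(length(read_peaklist(f3)$peaks), 0)
  f4 <- withr::local_tempfile()
  writeLines(c("A5HN-A5N 8.12 119.3 1 2 3 4"), f4)
  expect_error(read_peaklist(f4), "line 1")
})

test_that("constraint files round-trip in both dialects with the stated formats", {
  con <- constraint_table(5, "HA", 9, "HN", upper = 5.0,
                          res_type_i = "ALA", res_type_j = "VAL")
  f <- withr::local_tempfile(fileext = ".upl")
  write_constraints(con, f, "dyana_upl")
  expect_identical(readLines(f),
                   "   5 ALA  HA       9 VAL  HN        5.00")
  fx <- withr::local_tempfile(fileext = ".tbl")
  write_constraints(con, fx, "xplor")
  expect_identical(
    readLines(fx),
    "assign (resid 5 and name HA)(resid 9 and name HN) 1.80 0.00 3.20")
  for (dialect in c("dyana_upl", "xplor")) {
    back <- read_constraints(if (dialect == "dyana_upl") f else fx,
                             dialect)
    expect_equal(back$res_i, 5L)
    expect_equal(back$atom_j, "HN")
    expect_equal(back$upper, 5.0)
  }
  # empty set -> empty file -> empty table
  f0 <- withr::local_tempfile()
  write_constraints(empty_constraints(), f0, "dyana_upl")
  expect_equal(nrow(read_constraints(f0, "dyana_upl")), 0)
})

test_that("NMR-STAR chemical-shift loop writes and round-trips", {
  sh <- shift_table(c(1, 1, 2), c("ALA", "ALA", "LYS"),
                    c("HN", "N", "CA"), c(8.25, 120.4, 56.72),
                    sd = c(0.01, 0.1, 0.2))
  f <- withr::local_tempfile(fileext = ".str")
  write_shifts_nmrstar(sh, f)
  lines <- readLines(f)
  expect_true(any(grepl("loop_", lines)))
  expect_equal(sum(grepl("^\\s+[0-9]+ 1 ", lines)), 3)
  back <- read_shifts_nmrstar(f)
  expect_equal(back$shift, sh$shift, tolerance = 1e-4)
  expect_equal(back$atom_name, sh$atom_name)
  expect_error(write_shifts_nmrstar(sh[0, ], f), "empty")
  # randomized tables round-trip
  set.seed(11)
  for (r in 1:5) {
    n <- sample(3:20, 1)
    tab <- shift_table(seq_len(n), sample(c("ALA", "GLY", "TRP"), n, TRUE),
                       paste0("C", seq_len(n)),
                       round(runif(n, 0, 180), 4))
    f2 <- withr::local_tempfile()
    write_shifts_nmrstar(tab, f2)
    expect_equal(read_shifts_nmrstar(f2)$shift, tab$shift,
                 tolerance = 1e-4)
  }
})

test_that("multi-model PDB ensembles read back with one shared roster", {
  ens <- make_helix_ensemble(4, n_models = 2, jitter = 0.1, seed = 3)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble_pdb(ens, f)
  back <- read_ensemble_pdb(f)
  expect_equal(back$n_models, 2)
  expect_equal(nrow(back$atoms), nrow(ens$atoms))
  expect_equal(back$atoms$atom_name, ens$atoms$atom_name)
  expect_lt(max(abs(back$xyz - ens$xyz)), 1e-3)   # PDB prints 3 decimals
  # single model
  one <- make_helix_ensemble(3, n_models = 1)
  f1 <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble_pdb(one, f1)
  expect_equal(read_ensemble_pdb(f1)$n_models, 1)
  # roster mismatch reported with the first differing atom
  lines <- readLines(f)
  atom_lines <- which(startsWith(lines, "ATOM"))
  bad <- lines
  bad[atom_lines[length(atom_lines)]] <- sub(" O  ", " OX ",
                                             bad[atom_lines[length(atom_lines)]])
  f3 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(bad, f3)
  expect_error(read_ensemble_pdb(f3), "roster")
})
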