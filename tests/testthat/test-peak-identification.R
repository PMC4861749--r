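test_that("local-maximum picking matches the exhaustive oracle", {
  # degenerate cases
  zeros <- nmr_spectrum(list(ax_h(16), ax_n(16)), array(0, c(16, 16)))
  expect_equal(length(pick_local_maxima(zeros, pick_params(1))$peaks), 0)

  spike <- array(0, c(12, 12)); spike[5, 5] <- 10
  sp <- nmr_spectrum(list(ax_h(12), ax_n(12)), spike)
  got <- pick_local_maxima(sp, pick_params(5))
  expect_equal(length(got$peaks), 1)
  expect_equal(got$peaks[[1]]$position,
               c(axis_ppm(sp$axes[[1]], 5), axis_ppm(sp$axes[[2]], 5)))
  expect_equal(got$peaks[[1]]$height, 10)

  # well-separated Gaussians + noise against the brute-force oracle
  set.seed(101)
  for (rep in 1:5) {
    axes <- list(ax_h(48), ax_n(48))
    pos <- cbind(runif(20, 2, 7), runif(20, 105, 130))
    sigma <- 0.5
    spec <- make_spectrum(pos, runif(20, 20, 60) * sample(c(-1, 1), 20,
                                                          TRUE),
                          axes, noise_sigma = sigma, seed = rep)
    got <- pick_local_maxima(spec, pick_params(5 * sigma), refine = FALSE)
    oracle <- brute_force_maxima(spec$data, 5 * sigma)
    idx <- peak_grid_indices(got, spec)
    expect_equal(nrow(idx), nrow(oracle))
    expect_equal(idx[order(idx[, 1], idx[, 2]), , drop = FALSE],
                 oracle[order(oracle[, 1], oracle[, 2]), , drop = FALSE],
                 ignore_attr = TRUE)
  }
})

test_that("plateau ties resolve to a single peak at the lowest scan index", {
  a <- array(0, c(8, 8)); a[4, 4] <- a[5, 4] <- 7
  sp <- nmr_spectrum(list(ax_h(8), ax_n(8)), a)
  got <- pick_local_maxima(sp, pick_params(1), refine = FALSE)
  expect_equal(length(got$peaks), 1)
  expect_equal(peak_grid_indices(got, sp)[1, ], c(4L, 4L))
})

test_that("restricted picking keeps only peaks inside root windows", {
  axes <- list(ax_h(64), ax_n(32), ax_c(32))
  spec <- make_spectrum(rbind(c(8.0, 120.0, 56.2), c(8.5, 125.0, 30.0)),
                        c(50, 50), axes)
  roots <- hsqc_list(1, 8.0, 120.0)
  got <- restricted_pick(spec, roots, pick_params(5),
                         window = c(0.05, 0.5))
  expect_equal(length(got$peaks), 1)
  expect_equal(got$peaks[[1]]$position[3],
               56.2, tolerance = 0.5)
  expect_equal(got$peaks[[1]]$root, 1)
  # empty root list -> empty result
  expect_equal(length(restricted_pick(spec, nmr_peaklist(),
                                      pick_params(5))$peaks), 0)
  # restricted picks are a subset of the unrestricted pick
  all_peaks <- pick_local_maxima(spec, pick_params(5))
  expect_lte(length(got$peaks), length(all_peaks$peaks))
  # no axis mapping -> configuration error
  expect_error(restricted_pick(spec, roots, pick_params(5),
                               root_nuclei = c("31P", "15N")),
               "mapping")
})

test_that("height sorting is stable and by magnitude", {
  pl <- nmr_peaklist(list(nmr_peak(c(1, 1), height = 3),
                          nmr_peak(c(2, 2), height = -5),
                          nmr_peak(c(3, 3), height = 1)), 2)
  got <- sort_by_height(pl)
  expect_equal(vapply(got$peaks, function(p) p$height, numeric(1)),
               c(-5, 3, 1))
  expect_equal(length(sort_by_height(nmr_peaklist())$peaks), 0)
  # stable-sort oracle on random lists with ties
  set.seed(5)
  for (r in 1:10) {
    h <- sample(c(-3, -1, 1, 2, 3), 12, TRUE)
    pl <- nmr_peaklist(lapply(seq_along(h), function(i)
      nmr_peak(c(i, i), height = h[i])), 2)
    got <- vapply(sort_by_height(pl)$peaks, function(p) p$position[1],
                  numeric(1))
    expect_equal(got, seq_along(h)[order(-abs(h))])
  }
})

test_that("spin-system cross-validation flags orphan peaks as noise", {
  # same root in 3 spectra -> kept everywhere
  pls <- lapply(1:3, function(s) hsqc_list(1:4, c(7.1, 7.5, 8.0, 8.4),
                                           c(110, 115, 120, 125)))
  res <- flag_noise_by_spin_system(pls, pick_params(1))
  for (pl in res$peaklists)
    for (p in pl$peaks) expect_false("noise" %in% p$flags)
  # far-away orphan gets flagged, non-destructively
  pls[[1]]$peaks <- c(pls[[1]]$peaks, list(nmr_peak(c(9.4, 133), 1)))
  res <- flag_noise_by_spin_system(pls, pick_params(1))
  expect_true("noise" %in% res$peaklists[[1]]$peaks[[5]]$flags)
  expect_equal(length(res$peaklists[[1]]$peaks), 5)
  expect_equal(length(drop_flagged_peaks(res$peaklists[[1]])$peaks), 4)
  expect_error(flag_noise_by_spin_system(pls[1], pick_params()), "two")

  # planted orphans >= 3 tolerances from all clusters: exact recovery
  set.seed(21)
  for (r in 1:5) {
    n <- 20
    h <- seq(6.5, 9.5, length.out = n) # >= 0.15 ppm apart (3 x tol H is 0.06)
    nn <- seq(105, 130, length.out = n)
    a <- hsqc_list(1:n, h, nn)
    b <- hsqc_list(1:n, h + runif(n, -0.005, 0.005),
                   nn + runif(n, -0.05, 0.05))
    orphan_idx <- sample(n, 2)
    orphans <- lapply(orphan_idx, function(i)
      nmr_peak(c(h[i] + 0.075, nn[i] + 0.75), 1))  # 3+ tol from clusters
    a$peaks <- c(a$peaks, orphans)
    res <- flag_noise_by_spin_system(list(a, b), pick_params(1))
    flagged <- which(vapply(res$peaklists[[1]]$peaks, function(p)
      "noise" %in% p$flags, logical(1)))
    expect_equal(flagged, n + seq_along(orphan_idx))
  }
})

test_that("simulated assignments enumerate the expected correlations", {
  expect_equal(length(simulate_assignments(
    shift_table(integer(), character(), character(), numeric()),
    "N15HSQC")$peaks), 0)

  sh <- shift_table(c(1, 1, 2, 2), c("ALA", "ALA", "LYS", "LYS"),
                    c("CA", "CB", "HN", "N"),
                    c(52.0, 19.0, 8.1, 121.0))
  got <- simulate_assignments(sh, "CCONH")
  expect_equal(length(got$peaks), 2)
  expect_setequal(vapply(got$peaks, function(p) p$position[3], numeric(1)),
                  c(52.0, 19.0))
  for (p in got$peaks) {
    expect_equal(p$position[1:2], c(8.1, 121.0))
    expect_true("simulated" %in% p$flags)
    expect_true(all(grepl("_s$", p$assignment)))
  }

  # full 5-residue HSQC enumeration oracle
  n <- 5
  sh5 <- shift_table(rep(1:n, each = 2), "ALA",
                     rep(c("HN", "N"), n),
                     as.vector(rbind(seq(7, 9, length.out = n),
                                     seq(110, 125, length.out = n))))
  got5 <- simulate_assignments(sh5, "N15HSQC")
  expect_equal(length(got5$peaks), n)
  expect_equal(t(vapply(got5$peaks, function(p) p$position, numeric(2))),
               cbind(seq(7, 9, length.out = n),
                     seq(110, 125, length.out = n)),
               ignore_attr = TRUE)
})

test_that("center_peak snaps onto the nearest maximum and clears the tag", {
  axes <- list(ax_h(64), ax_n(64))
  spec <- make_spectrum(rbind(c(8.0, 120.0)), 50, axes)
  wide <- pick_params(1, tolerances = c(H = 0.2, N = 1, C = 1))
  near <- nmr_peak(c(8.0 + axis_step(axes[[1]]), 120.0), 0,
                   assignment = c("A3HN", "A3N"), flags = "simulated")
  got <- center_peak(spec, near, wide)
  expect_false("simulated" %in% got$flags)
  expect_false(any(grepl("_s$", got$assignment)))
  expect_equal(got$position[1], 8.0, tolerance = 0.02)
  # already centered: position unchanged
  at_max <- center_peak(spec, nmr_peak(c(8.0, 120.0), 0), wide)
  expect_equal(at_max$position, c(8.0, 120.0), tolerance = 0.02)
  # nothing within the window: unmoved, flag kept, warning
  far <- nmr_peak(c(4.0, 108.0), 0, flags = "simulated")
  expect_warning(kept <- center_peak(spec, far), "window")
  expect_equal(kept$position, c(4.0, 108.0))
  expect_true("simulated" %in% kept$flags)
})

test_that("pseudoatom merging averages positions and rewrites the label", {
  a <- nmr_peak(c(1.20), 5, assignment = "A7HB2")
  b <- nmr_peak(c(1.22), 5, assignment = "A7HB3")
  got <- merge_pseudoatom(a, b, tolerance = 0.02)
  expect_equal(got$position, 1.21)
  expect_equal(got$assignment, "A7QB")
  same <- merge_pseudoatom(nmr_peak(1.5, 1, assignment = "A2HB2"),
                           nmr_peak(1.5, 1, assignment = "A2HB3"))
  expect_equal(same$position, 1.5)
  expect_equal(same$assignment, "A2QB")
  # different pseudoatom groups refuse to merge
  expect_error(merge_pseudoatom(nmr_peak(1.5, 1, assignment = "A2HB2"),
                                nmr_peak(1.5, 1, assignment = "A2HG2")),
               "pseudoatom group")
  # non-overlapping positions refuse to merge
  expect_error(merge_pseudoatom(a, nmr_peak(1.5, 1, assignment = "A7HB3")),
               "overlap")
})

test_that("completeness report counts rosters and flags large deviations", {
  seqv <- c(`1` = "GLY", `2` = "ALA")
  sh <- shift_table(c(rep(1, 6), 2, 2),
                    c(rep("GLY", 6), "ALA", "ALA"),
                    c("N", "HN", "CA", "HA2", "HA3", "C", "N", "CA"),
                    c(108, 8.3, 45, 3.9, 3.7, 174, 122.9, 52),
                    sd = c(0.9, rep(0.01, 7)))
  rep <- completeness_report(sh, seqv)
  expect_equal(rep$residues$completeness[1], 1.0)   # all 6 Gly atoms
  expect_equal(rep$residues$assigned[2], 2)
  expect_equal(rep$residues$expected[2],
               length(residue_roster("ALA")))
  expect_true(rep$atoms$flagged[rep$atoms$atom_name == "N" &
                                rep$atoms$residue_index == 1]) # sd 0.9 ppm
  expect_false(any(rep$atoms$flagged[-1]))
})

test_that("statistical ellipses have chi-square geometry and coverage", {
  ell <- rna_statistical_ellipse(c(5.6, 92), diag(2), 0.95)
  expect_equal(ell$semi_axes, rep(sqrt(qchisq(0.95, 2)), 2),
               tolerance = 1e-12)
  expect_equal(ell$semi_axes[1], 2.4477, tolerance = 1e-4)
  expect_true(classify_peak_in_ellipse(c(5.6, 92), ell))
  expect_error(rna_statistical_ellipse(c(0, 0),
                                       matrix(c(1, 2, 2, 1), 2), 0.9),
               "positive-definite")
  # Monte-Carlo coverage at the nominal level
  set.seed(99)
  S <- matrix(c(0.04, 0.015, 0.015, 0.25), 2)
  ell2 <- rna_statistical_ellipse(c(7.8, 140), S, 0.9)
  L <- chol(S)
  z <- matrix(rnorm(2e5), ncol = 2) %*% L
  pts <- sweep(z, 2, c(7.8, 140), `+`)
  inside <- mahalanobis(pts, c(7.8, 140), S) <= ell2$q
  expect_equal(mean(inside), 0.9, tolerance = 0.01)
  # membership agrees with the quadratic-form definition peak by peak
  for (i in 1:50)
    expect_equal(classify_peak_in_ellipse(pts[i, ], ell2), inside[i])
})
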