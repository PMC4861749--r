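rotate_ensemble <- function(ens, angle = pi / 2, shift = c(5, -3, 2)) {
  Rz <- matrix(c(cos(angle), sin(angle), 0,
                 -sin(angle), cos(angle), 0,
                 0, 0, 1), 3, 3)
  ens$xyz[, , 2] <- t(Rz %*% t(matrix(ens$xyz[, , 2], ncol = 3))) +
    matrix(shift, nrow(ens$atoms), 3, byrow = TRUE)
  ens
}

test_that("superposition removes rigid motions and identical models give zero RMSD", {
  ens <- make_helix_ensemble(8, n_models = 3, jitter = 0)
  prof <- ca_rmsd_profile(ens)
  expect_true(all(prof$ca_rmsd < 1e-9))
  # model 2 rotated 90 degrees and translated: still zero after fitting
  rot <- rotate_ensemble(make_helix_ensemble(8, n_models = 2))
  prof2 <- ca_rmsd_profile(rot)
  expect_true(all(prof2$ca_rmsd < 1e-6))
  # planted displacement delta on half the models matches the closed form:
  # mean is delta/2 away from both halves -> rmsd = delta/2
  # analytic case: displacing one CA by delta in half the models makes its
  # per-model deviations +/- delta/2, hence RMSD = delta/2.  A long chain
  # keeps the refit perturbation negligible.
  delta <- 0.8
  pl <- make_helix_ensemble(80, n_models = 4)
  target <- pl$atoms$residue_index == 40 & pl$atoms$atom_name == "CA"
  for (m in 3:4) pl$xyz[target, 1, m] <- pl$xyz[target, 1, m] + delta
  prof3 <- ca_rmsd_profile(pl)
  expect_equal(prof3$ca_rmsd[prof3$residue_index == 40], delta / 2,
               tolerance = 0.03)
  expect_true(all(prof3$ca_rmsd[prof3$residue_index != 40] < 0.03))
})

test_that("contact map thresholds at the cutoff and matches brute force", {
  expect_true(contact_map(two_proton_ensemble(5.4))$contact[1, 2])
  expect_false(contact_map(two_proton_ensemble(5.6))$contact[1, 2])
  expect_equal(contact_map(two_proton_ensemble(3.0))$distance[2, 1], 3.0)
  # no hydrogens -> error
  noH <- make_helix_ensemble(4, n_models = 1)
  noH$atoms <- noH$atoms[noH$atoms$element != "H", ]
  noH$xyz <- noH$xyz[make_helix_ensemble(4, n_models = 1)$atoms$element
                     != "H", , , drop = FALSE]
  expect_error(contact_map(nmr_ensemble(noH$atoms, noH$xyz)),
               "hydrogens")
  # brute-force oracle on a jittered 5-residue ensemble
  ens <- make_helix_ensemble(5, n_models = 2, jitter = 0.2, seed = 9)
  cm <- contact_map(ens)
  hs <- which(ens$atoms$element == "H")
  for (a in 1:5) for (b in 1:5) {
    if (a == b) next
    want <- Inf
    for (m in 1:2) {
      xyz <- matrix(ens$xyz[, , m], ncol = 3)
      for (i in hs[ens$atoms$residue_index[hs] == a])
        for (j in hs[ens$atoms$residue_index[hs] == b])
          want <- min(want, sqrt(sum((xyz[i, ] - xyz[j, ])^2)))
    }
    expect_equal(cm$distance[a, b], want)
    expect_equal(cm$distance[b, a], want)
  }
  expect_true(all(is.na(diag(cm$distance))))
})

test_that("NOE bar chart classes split at |i-j| = 1 and 4 and conserve counts", {
  seqv <- setNames(rep("ALA", 12), 1:12)
  con <- constraint_table(res_i = c(5, 5, 5, 2),
                          atom_i = c("HA", "HA", "HA", "HN"),
                          res_j = c(6, 9, 11, 2),
                          atom_j = c("HN", "HN", "HN", "HA"),
                          upper = 5)
  bars <- noe_bar_chart(con, seqv)
  expect_equal(bars$short[bars$residue_index == 6], 1)   # |5-6| = 1
  expect_equal(bars$medium[bars$residue_index == 9], 1)  # |5-9| = 4
  expect_equal(bars$long[bars$residue_index == 11], 1)   # |5-11| = 6
  expect_equal(bars$short[bars$residue_index == 2], 2)   # intra, both ends
  expect_equal(sum(bars[, c("short", "medium", "long")]), 2 * nrow(con))
})

test_that("violation report measures upper/lower breaches per model", {
  ens <- two_proton_ensemble(4.0)
  con <- constraint_table(1, "HA", 5, "HA", upper = 5.0)
  vr <- violation_report(ens, con)
  expect_equal(vr$mean_viol, 0)
  expect_false(vr$flagged)
  ens6 <- two_proton_ensemble(6.0)
  vr6 <- violation_report(ens6, con)
  expect_equal(vr6$max_viol, 1.0)
  expect_true(vr6$flagged)
  # ensemble of 3 models at distances 4, 5, 7 against upper 5
  atoms <- two_proton_ensemble(1)$atoms
  xyz <- array(0, c(2, 3, 3))
  xyz[2, 1, ] <- c(4, 5, 7)
  vr3 <- violation_report(nmr_ensemble(atoms, xyz), con)
  expect_equal(vr3$max_viol, 2.0)
  expect_equal(vr3$mean_viol, 2 / 3)
  # lower-bound breach
  close <- violation_report(two_proton_ensemble(1.0), con)
  expect_equal(close$mean_viol, 0.8)
})

test_that("pseudoatom distances use r^-6 averaging over member protons", {
  atoms <- data.frame(residue_index = c(1, 1, 5),
                      residue_type = c("LYS", "LYS", "ALA"),
                      atom_name = c("HB2", "HB3", "HA"),
                      element = "H", stringsAsFactors = FALSE)
  xyz <- array(c(0, 0, 3,   0, 1, 0,   0, 0, 0), c(3, 3, 1))
  ens <- nmr_ensemble(atoms, xyz)
  con <- constraint_table(1, "QB", 5, "HA", upper = 10)
  vr <- violation_report(ens, con)
  d1 <- 3; d2 <- sqrt(9 + 1)
  expect_equal(vr$mean_dist, mean(c(d1^-6, d2^-6))^(-1 / 6),
               tolerance = 1e-9)
  vc <- violation_report(ens, con, pseudo_method = "center")
  expect_equal(vc$mean_dist, sqrt(sum((c(0, 0.5, 0) - c(3, 0, 0))^2)),
               tolerance = 1e-9)
})

test_that("Ramachandran grid uses 4-degree voxels with wrap-around", {
  expect_equal(rama_voxel(0), 46)     # [0, 4) is the 46th 1-based voxel
  expect_equal(rama_voxel(-180), 1)
  expect_equal(rama_voxel(180), 1)    # wraps to -180
  expect_equal(rama_voxel(179.99), 90)
  ens <- make_helix_ensemble(6, n_models = 3)
  rg <- rama_grid(ens)
  expect_equal(dim(rg$grids$all), c(90, 90))
  # total counts = (#residues with both dihedrals) x #models
  expect_equal(sum(rg$grids$all), 4 * 3)
  expect_equal(rg$n_obs, sum(rg$grids$all))
  # stratified grids sum to the unstratified grid
  for (strat in c("residue_type", "ss_type")) {
    rs <- rama_grid(ens, strat)
    expect_equal(Reduce(`+`, rs$grids), rg$grids$all)
  }
  # dihedral dispersion: zero jitter -> zero circular sd
  disp <- rama_dispersion(ens, 3)
  expect_equal(unname(disp), c(0, 0), tolerance = 1e-6)
  jit <- rama_dispersion(make_helix_ensemble(6, n_models = 10,
                                             jitter = 0.05, seed = 2), 3)
  expect_true(all(jit > 0))
})

test_that("RDC tensor fitting recovers a known alignment from clean data", {
  ens <- make_helix_ensemble(14, n_models = 1)
  truth <- c(3, -1, 2, 1, -2)
  rd <- make_rdc_set(ens, truth)
  fit <- fit_rdc_tensor(ens, rd$rdc, model = 1)
  expect_lt(fit$q_factor, 1e-10)
  expect_equal(fit$tensor$saupe, truth, tolerance = 1e-8)
  expect_equal(fit$pearson_r, 1, tolerance = 1e-10)
  expect_equal(sum(diag(fit$tensor$S)), 0, tolerance = 1e-12) # traceless
  # fewer than 5 records refuse
  expect_error(fit_rdc_tensor(ens, rd$rdc[1:4, ]), "at least 5")
  # Q invariant under a global sign flip of the observations
  flip <- rd$rdc; flip$d_obs <- -flip$d_obs
  expect_equal(fit_rdc_tensor(ens, flip, model = 1)$q_factor,
               fit$q_factor, tolerance = 1e-12)
  # Q grows with noise
  qs <- vapply(c(0.5, 2), function(s)
    fit_rdc_tensor(ens, make_rdc_set(ens, truth, noise_sigma = s,
                                     seed = 11)$rdc, model = 1)$q_factor,
    numeric(1))
  expect_true(qs[1] < qs[2])
})

test_that("classifier boundaries match the published color modes", {
  expect_equal(classify_rdc_violation(c(0, 1.49, 1.5, 2.999, 3.0, 4.49,
                                        4.5, 10)),
               c("green", "green", "blue", "blue", "purple", "purple",
                 "red", "red"))
  fl <- classify_flexibility(c(0, 0.75, 1.5, 1.7, 2.0, 3))
  expect_equal(fl$class, c("gradient", "gradient", "gradient", "gradient",
                           "red", "red"))
  expect_equal(fl$fraction, c(0, 0.5, 1, 1, 1, 1))
  hy <- classify_hydrophobicity(c(5, 10, 20, 30, 95))
  expect_equal(hy$class, c("red", "gradient", "gradient", "blue", "blue"))
  expect_equal(hy$fraction, c(0, 0, 0.5, 1, 1))
  expect_equal(classify_secondary_structure(-60, -45), "helix")
  expect_equal(classify_secondary_structure(-120, 130), "strand")
  expect_equal(classify_secondary_structure(60, 60), "loop")
})

test_that("solvent-accessible surface matches closed forms and converges", {
  one <- nmr_ensemble(data.frame(residue_index = 1, residue_type = "ALA",
                                 atom_name = "CA", element = "C"),
                      array(c(0, 0, 0), c(1, 3, 1)))
  sa <- sas_profile(one)
  expect_equal(sa$sas, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.02)
  # atom inside a tight cage of neighbors is fully buried
  cage_dirs <- rbind(diag(3), -diag(3))
  atoms <- data.frame(residue_index = c(1, rep(2, 6)),
                      residue_type = "ALA",
                      atom_name = c("CA", paste0("C", 1:6)),
                      element = "C", stringsAsFactors = FALSE)
  xyz <- array(t(rbind(c(0, 0, 0), cage_dirs * 1.8)), c(3, 7, 1))
  cage <- nmr_ensemble(atoms, array(aperm(xyz, c(2, 1, 3)), c(7, 3, 1)))
  expect_equal(sas_profile(cage)$sas[1], 0, tolerance = 1e-9)
  # doubling the point count changes totals by < 1%
  ens <- make_helix_ensemble(6, n_models = 1)
  s1 <- sum(sas_profile(ens, n_points = 960)$sas)
  s2 <- sum(sas_profile(ens, n_points = 1920)$sas)
  expect_lt(abs(s1 - s2) / s2, 0.01)
})

test_that("residue analysis joins the per-residue columns consistently", {
  ens <- make_helix_ensemble(8, n_models = 3, jitter = 0.15, seed = 6)
  hb <- hbond_constraints(detect_hbonds(ens))
  rd <- make_rdc_set(ens, c(3, -1, 2, 1, -2), noise_sigma = 1, seed = 2)
  prof <- residue_analysis(ens, hb, rd$rdc)
  expect_equal(nrow(prof), 8)
  expect_true(all(c("ca_rmsd", "phi", "psi", "ss_class", "hydrophobicity",
                    "sas", "short", "medium", "long", "rdc_violation",
                    "flex_class", "hydro_class", "rdc_class")
                  %in% names(prof)))
  # columns equal the individually computed profiles
  expect_equal(prof$ca_rmsd, ca_rmsd_profile(ens)$ca_rmsd)
  expect_equal(prof$sas, sas_profile(ens, n_points = 240)$sas)
  bars <- noe_bar_chart(hb, ens$sequence)
  expect_equal(prof$short, bars$short)
  # interior of an ideal helix classifies as helix
  expect_true(all(prof$ss_class[3:6] == "helix"))
  # deterministic across runs
  prof2 <- residue_analysis(ens, hb, rd$rdc)
  expect_identical(prof, prof2)
})

test_that("viewer scripts are deterministic and reflect the classifiers", {
  ens <- make_helix_ensemble(5, n_models = 2)
  prof <- residue_analysis(ens)
  # all-zero RMSD: every residue pure green under @cf
  expect_true(all(grepl("0x00ff00",
                        strsplit(emit_viewer_script("@cf", prof),
                                 "\n")[[1]])))
  # one >= 4.5 Hz violation: exactly one red command under @cr
  prof$rdc_class <- c(NA, NA, "red", NA, NA)
  script <- strsplit(emit_viewer_script("@cr", prof), "\n")[[1]]
  expect_equal(sum(grepl("0xff0000", script)), 1)
  expect_equal(length(script), 5)
  # byte-for-byte idempotent
  expect_identical(emit_viewer_script("@sc", prof),
                   emit_viewer_script("@sc", prof))
  con <- constraint_table(2, "HA", 4, "HN", upper = 5)
  expect_match(emit_viewer_script("@p", constraint = con),
               "resi 2 and name HA")
  expect_error(emit_viewer_script("@zz"), "unknown viewer mode")
})
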