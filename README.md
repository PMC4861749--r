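# nmrstructkit

Desk-scale computational toolkit for protein NMR structure determination
workflows, for spectroscopists and structural biologists who want the
analysis steps between "processed spectra" and "validated ensemble" as
scriptable, tested R functions rather than GUI clicks:

* **Spectral I/O** — Sparky UCSF binary spectra (2D–4D, tiled), Sparky
  `.list` peak lists, minimal NMR-STAR v3 chemical-shift loops, DYANA
  `.upl` / Xplor distance restraints, multi-model PDB ensembles.
* **Peak identification** — local-maxima picking above a contour floor
  with parabolic sub-grid refinement, restricted (root-window) picking of
  3D spectra from HSQC roots, height sorting, cross-spectrum spin-system
  noise flagging, predict-and-confirm simulated assignments, pseudoatom
  merging, assignment-completeness reports, RNA statistical shift
  ellipses.
* **Spectral series** — chemical-shift perturbation (single-nucleus and
  composite), titration traces, exponential relaxation fits, per-residue
  and per-spectrum intensity profiles, deterministic SVG charts.
* **Distance constraints** — NOE intensity calibration by the
  inverse-power law, automatic noise-threshold estimation at the 5.5 Å
  cutoff, candidate assignment with blacklist/whitelist pair weighting,
  continuous or binned bound generation with pseudoatom corrections,
  hydrogen-bond detection and constraint emission.
* **Ensemble validation** — iterative-mean Cα superposition and RMSD
  profiles, inter-proton contact maps, NOE bar charts, distance-violation
  reports with r⁻⁶ pseudoatom averaging, Ramachandran voxel densities,
  RDC alignment-tensor SVD fits with Q-factors, solvent-accessible
  surface, per-residue classifiers and PyMOL-style viewer scripts.
* **Fixtures** — seed-deterministic generators (ideal helices, synthetic
  spectra, NOE/RDC sets, titration/decay series) that return their ground
  truth, so the whole pipeline is testable offline.

## The core quantities

NOESY cross-peak intensities fall off with inter-proton distance *r*
approximately as

&nbsp;&nbsp;&nbsp;&nbsp;*I* = *c* · *r*⁻ᵏ, *k* ∈ [3, 6] (default 6),

so after pinning a reference percentile of the intensity distribution to
a reference distance (median ↔ 3.0 Å by default), every intensity inverts
to a distance *d*(*I*) = (*c*/*I*)^(1/k). Upper bounds are *d*(*I*) plus
a 0.5 Å pad and pseudoatom corrections; the noise floor is the intensity
corresponding to 5.5 Å, beyond which no cross peak is expected. RDC
agreement is summarized by the quality factor
Q = rms(D<sub>calc</sub> − D<sub>obs</sub>) / rms(D<sub>obs</sub>) after a
singular-value fit of the five Saupe tensor elements.

## Worked example

```r
library(nmrstructkit)

# 20-model ensemble of an ideal 12-residue helix with 0.25 A jitter
ens <- make_helix_ensemble(12, n_models = 20, jitter = 0.25, seed = 42)

# synthetic NOESY built from its proton distances (I = c * r^-6)
noe <- make_noe_set(ens, c = 1e6, k = 6, seed = 42)
h   <- vapply(noe$peaks$peaks, function(p) p$height, numeric(1))
estimate_noise_threshold(h, noe$calibration)
#> <intensity_threshold> I_cut = 36.1263 at 5.50 A (robust:51 mixed:38 noise:0)

# assign peaks, convert intensities to bounds, check against the models
asg <- assign_noe_candidates(noe$peaks, noe$shifts)
con <- generate_distance_constraints(asg, noe$calibration)
nrow(con)
#> [1] 89
vr <- violation_report(ens, con)
sum(vr$flagged)
#> [1] 9

# one table per residue: RMSD, dihedrals, SS class, SAS, NOE counts
head(residue_analysis(ens, con)[, c("residue_index", "ca_rmsd", "phi",
                                    "psi", "ss_class", "sas", "short",
                                    "medium")], 3)
#>   residue_index   ca_rmsd       phi       psi ss_class      sas short medium
#> 1             1 0.3782828        NA -27.16634     loop 98.78101     2      3
#> 2             2 0.3605372 -62.52251 -60.04107    helix 79.40032     6      6
#> 3             3 0.4261766 -54.05378 -54.04673    helix 75.68891     8      5
```

The threshold line says: with the generating calibration, the intensity
floor corresponding to 5.5 Å is 36.1; 51 peaks are in the robust range
(closer than 4.5 Å), 38 sit where real peaks and noise mix, and none fall
below the floor (the fixture plants no noise). The nine flagged
constraints are model-1 distances that the 0.25 Å inter-model jitter
pushes past their bounds in some models — exactly what the violation
report is for. A relaxation series round-trips the same way:

```r
ser <- make_series("decay", n_residues = 5, noise = 0.02, seed = 3)
fit_decay(ser$series, 2)
#> <decay_fit> I0 = 100.5, R = 1.304 /s (T = 0.7666 s), rms 1.62
ser$truth$R[2]
#> [1] 1.26902
```

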