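---
title: "Methods: from NOESY spectra to validated ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from NOESY spectra to validated ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrstructkit)
```

This vignette is the package's own account of the models and procedures
it implements, the parameters that matter, and the choices made where
the underlying conventions are genuinely open.

## Spectra, axes and peak picking

A spectrum is a dense real grid with per-axis ppm calibration. The ppm
scale follows the standard display convention — ppm decreases with
increasing grid index, index 1 at the downfield edge — and index↔ppm
conversion is a bijection on grid points. Only the canonical Sparky UCSF
layout is read (big-endian 32-bit floats, single component, 128-byte
axis headers, row-major tiles with the last axis fastest); any other
variant is rejected rather than guessed, because silently misreading a
spectrum is worse than refusing it.

Peak picking returns every grid point whose absolute intensity clears
the contour floor and beats all of its 3^N − 1 neighbors. Two numerical
choices:

* **Plateau ties** go to the lowest scan index, so a flat-topped peak
  yields exactly one pick instead of none (strict comparison) or many
  (non-strict).
* **Sub-grid refinement** fits a three-point parabola per axis to the
  absolute intensity and shifts the position by at most half a grid
  step. This mirrors what interactive peak pickers do and reduces the
  discretization error of the reported ppm.

Restricted picking searches only inside windows centered on 2D root
peaks (root position ± tolerance on the two shared axes, the full range
on the third). Default match tolerances are 0.02 ppm for ¹H and 0.2 ppm
for ¹⁵N/¹³C — the usual order of magnitude for matched, well-referenced
spectra; all are configurable because they should track the real
linewidths at hand.

Cross-spectrum noise flagging clusters root (HN, N) coordinates across
peak lists and keeps peaks whose cluster is supported by at least 2
distinct spectra. A real amide appears in every ¹⁵N-rooted experiment;
a noise spike does not. Flagging is non-destructive — deletion is an
explicit second step — so a flag can be reviewed before anything is
lost. The exact grouping heuristics of interactive spin-system tools are
not published; the support rule here is a documented, testable stand-in.

## Simulated assignments and completeness

The predict-and-confirm helpers enumerate the expected correlations of
an experiment from a shift table (e.g. C(CO)NH: amide (HNᵢ, Nᵢ) against
every aliphatic carbon of residue i−1), tag each simulated peak with a
`"_s"` label suffix, and later snap it onto the nearest observed maximum
while detaching the tag. The completeness report counts assigned atoms
against a per-residue-type roster in which chemically equivalent proton
groups appear once under their DYANA pseudoatom name, and flags shift
entries whose standard deviation exceeds 0.05 ppm (¹H) or 0.5 ppm
(¹³C/¹⁵N) — spreads that usually indicate an inconsistent assignment
rather than genuine exchange behavior.

RNA assignment ellipses are plain bivariate-Gaussian confidence regions:
the covariance eigen-decomposition scaled by the chi-square quantile
with 2 degrees of freedom, membership by squared Mahalanobis distance.
Published base-specific statistics are not bundled; the ellipse takes
whatever mean/covariance table the user supplies.

## Series analytics

Chemical-shift perturbation supports the composite form
√(Δδ_H² + (w·Δδ_X)²) with w = 0.14 for ¹⁵N and 0.25 for ¹³C — the
weights in widespread community use, exposed as parameters since no
single convention is universal. Residues present in only one condition
are reported as missing, never as zero, because a vanished peak is
signal, not absence of change.

Relaxation decays are fitted to the mono-exponential
I(t) = I₀·e^(−Rt) by Levenberg–Marquardt least squares initialized from
a log-linear regression, with I₀ > 0 and R ≥ 0 enforced. An additive
offset term is available behind a flag but off by default: with typical
8–12 point decays the offset is poorly determined and mostly absorbs
noise. Exactly flat series short-circuit to the closed-form optimum
(I₀ = mean, R = 0), where the iterative fit's gradient test is
degenerate. Fits are refused, with a diagnostic, for fewer than 3
points or non-positive heights.

Charts are emitted as hand-built SVG with fixed geometry constants and
fixed number formatting, so identical input yields byte-identical files
and tests can count the drawn elements.

## NOE calibration and distance bounds

Cross-relaxation makes NOESY intensities decay approximately as r⁻⁶ for
rigid pairs; exponents down to 3 accommodate dynamics and spin
diffusion. The calibration pins a reference percentile of the absolute
intensities to a reference distance, c = I_p · d_ref^k, with defaults
median ↔ 3.0 Å: the median NOE in a folded protein is a short-range
contact of roughly that length, and a percentile is robust against a few
mis-picked giants. The noise threshold is the intensity corresponding to
5.5 Å — the distance beyond which cross peaks are not expected — and
peaks are zoned robust (≤ 4.5 Å equivalent), mixed, or noise. The 4.5 Å
robust boundary is a package choice marking the range where observed
intensity is rarely noise; it is a flag, not a physical constant.

Bounds are upper = d(I) + 0.5 Å, lower = 1.8 Å (van der Waals contact).
Pseudoatoms get the standard DYANA corrections on the upper bound:
+1.0 Å for methyls (and NH₃), +0.7 Å for other equivalent-proton groups.
The binned mode classes unambiguous peaks by intensity terciles into
strong/medium/weak with uppers 2.8/3.5/5.0 Å, the long-standing manual
classification; ties fall to medium so an all-equal set makes no strong
claims. Candidate assignment stops at tolerance matching plus
blacklist/whitelist resolution: demoted residue pairs are removed, a
unique promoted pair wins ties, anything else stays explicitly
ambiguous. Network-anchored or structure-iterative disambiguation is
deliberately out of scope.

Hydrogen bonds are detected geometrically (H···O < 2.5 Å, N···O < 3.5 Å,
N–H···O angle > 120°) and must persist in at least half the models —
single-model contacts in a jittered bundle are noise. Each bond emits
the conventional pair of constraints: HN–O 1.8–2.3 Å and N–O 2.8–3.3 Å.

## Ensemble validation

Superposition iterates Kabsch fits of every model onto the running mean
over Cα atoms until the mean moves less than 10⁻⁶ Å; per-residue RMSD is
measured about that mean. Contact maps report the minimum inter-proton
distance per residue pair over all models, thresholded at 5.5 Å — the
same distance horizon as the NOE analysis, so the map predicts where
cross peaks should appear. Violation checks use r⁻⁶ averaging over
pseudoatom member protons (the physically appropriate mean for NOE
distances; plain center averaging is available behind a flag) and flag
constraints whose mean violation exceeds 0.1 Å or whose worst model
exceeds 0.5 Å.

Ramachandran densities count (residue, model) φ/ψ observations in 4°×4°
voxels over [−180°, 180°), lower edge inclusive, φ = −180° wrapping to
the first voxel; grids can be stratified by residue type or by a
dihedral-region secondary-structure rule, and stratified grids sum
exactly to the unstratified one. Per-residue dihedral dispersion is the
circular standard deviation across models.

The RDC fit solves D = A·s for the five independent Saupe elements by
SVD of the design matrix of unit bond vectors, refusing rank-deficient
systems (fewer than 5 records, or bond vectors too collinear to
determine all five elements; the amide N–H vectors of a helix precess
on a cone about the axis and are sufficient). The fit operates on the
mean structure by default or any chosen model.
Q = rms(D_calc − D_obs)/rms(D_obs).

Solvent-accessible surface uses Shrake–Rupley sphere sampling with a
1.4 Å water probe and 960 deterministic golden-spiral points per atom
(2% accuracy on an isolated atom; halving the error costs double the
points). Bondi van der Waals radii are used per element.

Per-residue classifiers implement the viewer color modes: RDC violation
bins [0,1.5)/[1.5,3)/[3,4.5)/[4.5,∞) Hz; flexibility red at ≥ 2.0 Å
mean Cα RMSD with a green→red gradient over 0–1.5 Å, clamped between
1.5 and 2.0 Å where the published mode leaves the interval undefined;
hydrophobicity red below 10%, blue at ≥ 30%, linear between. The
hydrophobicity percentage basis is not standardized anywhere, so the
package defines it as Kyte–Doolittle hydropathy min–max normalized to
0–100 over the 20 standard residues and ships it as an editable table.

## Synthetic data: what it does and does not emulate

Every generator is seed-deterministic and returns its ground truth. The
helix builder places backbone atoms by standard covalent geometry at
φ = −57°, ψ = −47° with amide protons on the C′–N/Cα–N bisector; its
interior residues form the i→i−4 hydrogen bonds of a real α-helix, and
per-model Gaussian jitter emulates the coordinate spread of an NMR
bundle. Synthetic NOESY sets apply the exact r⁻ᵏ law to model-1
distances with distinct proton shifts on a 0.05-ppm grid.

What this does **not** emulate: spin diffusion and relaxation-matrix
effects (intensities are exactly r⁻ᵏ), shift overlap/degeneracy (shifts
are planted collision-free), baseline distortions and ridge artifacts
in spectra, and conformational exchange. Passing tests therefore
demonstrate correctness of the algorithms under their stated models,
not robustness to every pathology of real data — thresholds and
tolerances remain knobs the practitioner must set against real spectra.

Test and acceptance problem sizes (helices of 4–16 residues, 16–64
point grids, 20-model bundles, 200-peak calibration sets, 1000-replicate
noise studies) were chosen as the smallest sizes at which every check is
statistically meaningful.

## Known limitations

Single-chain proteins only; no NMRPipe/Bruker spectrum formats; no
automated NOESY assignment beyond candidate enumeration; no
structure calculation; NMR-STAR support is the chemical-shift loop, not
full entries; secondary-structure classification is a dihedral-region
rule with an H-bond override, not DSSP.
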