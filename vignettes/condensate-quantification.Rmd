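---
title: "Quantifying proteins in sub-resolution condensates with pbquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying proteins in sub-resolution condensates with pbquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbquant)
```

## The measurement problem

Membrane-less condensates such as yeast P bodies concentrate specific
proteins out of the cytoplasm. Two numbers characterize each resident
protein: its absolute concentration inside the condensate (µM) and its
partition coefficient PC = C_pbody / C_cyto. Both are hard to measure
because P bodies (0.3–0.8 µm) sit at or below the resolution of a confocal
microscope: the point spread function (PSF) smears a P body's fluorescence
into the surrounding volume, so its peak pixel under-reports the true
concentration by a factor that depends steeply on the object's size.

`pbquant` implements the full measurement chain: PSF estimation from bead
stacks, a sphere-convolution dilution-correction curve, MaxEntropy/Otsu
segmentation, GFP standard-curve calibration, partition coefficients,
molecule-count bookkeeping, FRAP/iFRAP exchange kinetics, co-partitioning
statistics and interaction-network centrality — plus a synthetic-data
generator with known ground truth that lets every stage be validated
end to end.

## The dilution correction

The PSF is modelled as a separable anisotropic Gaussian with standard
deviations `sigma_x = sigma_y` (lateral) and `sigma_z` (axial); defaults in
this document are 0.13 µm and 0.34 µm (lateral FWHM 0.31 µm, axial
0.80 µm), and `estimate_psf_from_beads()` recovers them from 0.2 µm bead
stacks with the bead's finite size removed by quadrature subtraction of its
Gaussian-equivalent sd (d/4).

Convolving a unit-intensity ball of diameter d with the normalized PSF
gives, at the ball centre, the fraction of true peak intensity that
survives blurring — the correction factor CF(d). We reduce the ball
integral to nested 1-D quadratures (slices along one axis; the
cross-sectional disk mass of the bivariate normal integrates analytically
in one direction) and validate it against Monte-Carlo ball integration and,
for isotropic PSFs, the closed-form chi-squared(3) probability.

Only the increment of the P body over the cytoplasm is corrected, because
the cytoplasmic contribution is homogeneous and not diluted:

    I_pbody = (I_pbody,measured - I_cyto) / CF + I_cyto

Two practical conventions matter, and the curve models both when built
with a `voxel_size`:

* **Pixel integration.** A camera voxel records the box average of the
  blurred scene, not a point sample. The `cf` column is then the exact box
  average of the convolved-sphere model over the centre voxel, and the
  apparent diameter uses the detection PSF (optics widened in quadrature
  by the voxel box, sigma_eff^2 = sigma^2 + p^2/12).
* **Nine-pixel averaging.** The measured peak is the mean of the max pixel
  and its one-pixel circle, which reads below the centre value for objects
  near the PSF size. The `cf_ninepixel` column corrects exactly that
  reading, and `quantify_object()` prefers it when present.

Lookups are indexed by the *apparent* (blurred, measured) FWHM, not the
true diameter, because the pipeline only ever observes blurred sizes; the
curve stores both columns so either convention can be tested. The mapping
is strictly monotone but not inflationary everywhere: blur widens objects
below the lateral FWHM, while intermediate spheres (roughly 1–4x the FWHM)
measure slightly *small* at half maximum because their peak has not yet
saturated. Objects whose measured FWHM is below 1.1x the lateral PSF FWHM
(0.33 µm at a 0.30 µm FWHM) carry no reliable size information and are
rejected.

```{r curve}
psf <- psf_model(0.13, sigma_z = 0.34)
curve <- build_correction_curve(psf, seq(0.1, 1.2, by = 0.1),
                                voxel_size = c(0.05, 0.05, 0.2))
head(as.data.frame(curve), 4)
```

## Segmentation choices

P bodies are found by Kapur MaxEntropy thresholding (256 uniform bins over
the intensity range, the Fiji convention) of the measurement channel, or of
an mCherry marker channel whose mask is transferred to the measurement
channel — the marker also supplies the size measurement, which is what
rescues weakly partitioned cargo (PC near 2) whose own signal is
sub-threshold. Components use 26-connectivity.

Cell boundaries come from Otsu thresholding of the cytoplasmic signal.
Plain Otsu fails on condensate-bearing images: the rare ultra-bright voxels
dominate the between-class variance and push the threshold above the
cytoplasm. `segment_cells()` therefore iteratively strips sparse bright
tails (re-applying MaxEntropy while the foreground fraction stays under
10%) before running Otsu on the remainder, which then cuts between
background and cytoplasm near mid-amplitude — where the blurred cell edge
lies. Axis diameters are the mask extents along x, y, z through the
centroid; with a 0.34 µm axial sigma the recovered axes are accurate to
roughly two voxels (the Otsu cut sits slightly below mid-amplitude when
class weights are unequal), and cells in the bottom and top 10% of mean
GFP intensity are discarded as expression outliers (floor(0.1 n) per tail,
ties broken by stable input order).

The local cytoplasm baseline for FWHM measurement is the density mode of
in-cell voxels near the object (excluding the thresholded mask and a
0.5 µm halo): the mode ignores both the PSF tail and the darker blurred
cell edge. Cytoplasm intensity for quantification instead follows the
three-ROI convention: three circular ROIs of the object's diameter placed
at seeded-random positions in the cell mask eroded by two pixels, excluding
P-body masks dilated by two pixels, in the z-plane of the object's maximum.

## Molecule bookkeeping

Cells are treated as ellipsoids, V = 4/3 π (x/2)(y/2)(z/2), with 67% of the
volume cytoplasmic (a literature constant, exposed as
`CYTOPLASM_FRACTION`). Counts follow from volumes and concentrations via
Avogadro's number; the fraction sequestered is F_P = N_pbody /
(N_cyto + N_pbody). Because condensates below the detection limit are
invisible, F_P undercounts; `fp_max()` rescales by the most sequestered
reference protein, whose true fraction is taken as one. P-body volumes use
the PSF-corrected (true) diameter obtained by inverting the
apparent-diameter map (`true_diameter_from_apparent()`); the raw-FWHM
convention remains available by passing measured diameters directly.

## FRAP and iFRAP

Traces live on the post-bleach timebase (t = 0 at the first post-bleach
frame). Recovery normalization divides the background-subtracted ROI by the
background-subtracted unbleached reference frame by frame (removing
acquisition photobleaching), multiplies by the cytoplasm after/before ratio
(the bleach pulse also dims the cytoplasmic pool), and rescales so the
pre-bleach level is one. The pre-bleach scaling uses the first post-bleach
reference frame and no cytoplasm factor, since pre-bleach cytoplasm is by
definition unbleached; the published equations lost their division bars in
typesetting, and this reconstruction is dimensionless, equals one
pre-bleach, and reduces to standard double normalization when the cytoplasm
is unbleached. The alternative reading (before/after) is available via
`cyto_mode`. iFRAP decays are normalized to the first post-bleach frame.

Fits minimize least squares of I(t) = I_inf + (I0 - I_inf) exp(-k t) with
k constrained non-negative, initialized from the first point, the mean of
the last three points, and a log-linear slope, with five multi-starts
(k jittered by 0.5–2x) and an SSE tolerance of 1e-12. Flat traces return
zero fractional recovery with k flagged unidentifiable rather than an
error. Noiseless traces at the experimental cadence (5 s intervals for
150 s) round-trip generator parameters to 1e-6.

```{r frap}
kt <- kinetic_ground_truth(k = 0.041, frac = 0.85, I0 = 0.2)
trace <- generate_frap_trace(kt)
fit_recovery(trace$t, normalize_frap(trace))
```

## Co-partitioning statistics

Concentrations of two proteins measured in the same P bodies correlate if
they partition cooperatively. Besides the Pearson correlation, the package
implements the randomized-pairing null: ratios C_x,i / C_y,j with i and j
drawn uniformly with replacement, redrawn whenever i = j, keeping the
sample size. Breaking the pairing widens the ratio distribution, and the
widths are compared with the Fligner-Killeen test on log ratios (ratios
are scale-asymmetric; raw-ratio variances are reported alongside). The
Wilcoxon rank-sum test uses midranks with exact enumeration up to a
combined n of 12 and a tie- and continuity-corrected normal approximation
beyond. HC (highly concentrated) residents satisfy PC >= 30 and
C_pbody > 5 µM strictly; everything else is LC.

One power note: with the lognormal generator the log-ratio sd ratio between
randomized and paired sets is sqrt(1/(1-rho)) — independent of the spread —
so at rho = 0.65 and n = 86 the Fligner test at alpha = 0.001 rejects in
about 80% of replicates, reaching ~90% only toward rho = 0.70.

## Interaction network

The connection map is an undirected, unweighted graph of condensate
components (one node per protein, stable complexes such as Lsm1-7 collapsed
to a single node with union edge semantics, plus one RNA node). Valency is
the node degree; eigenvector centrality is computed by power iteration on
A + cI with a small spectral shift c = 0.05 x max degree, which leaves the
eigenvectors unchanged while guaranteeing convergence on bipartite
components (a damped teleport would bias the vector; the shift does not).
Disconnected graphs score the component containing the RNA node.

## The synthetic-data generator

`ground_truth()` + `generate_cell_stack()` emulate the statistical
structure of the study's imaging: ellipsoidal cells (4–6 µm axes) with
cytoplasmic concentrations of 0.05–0.5 µM, spherical P bodies of
0.33–0.8 µm at 1–20 µM (PC 2–250), the anisotropic Gaussian PSF above,
linear camera gain (400 a.u./µM) and offset (10 a.u.), Poisson shot noise
(20 photons per a.u., a bright-confocal budget at which the smallest/
dimmest study objects remain measurable) and Gaussian read noise
(1.5 a.u.). Spheres are rasterized with analytic sub-voxel coverage (5x
oversampled boundary voxels); cell ellipsoids use a half-voxel linear edge
ramp. Because real optics blur *before* the detector samples, rendering
happens on an internal z grid fine enough to avoid aliasing small spheres
(the axial step is subdivided up to 4x) and the blurred planes are averaged
back into camera voxels. Default voxel size is 0.05 µm laterally (blurred
profiles are well sampled; the nine-pixel convention then reads ~2% under
the peak rather than ~7% at 0.1 µm pixels) and 0.22–0.2 µm axially, the
study's z step.

What the generator does *not* emulate: non-Gaussian PSF tails and
refractive-index mismatch, depth-dependent aberrations, cell-to-cell
background structure (vacuoles, nuclei), P-body ellipticity, fusion
dynamics, and camera fixed-pattern noise. Passing the recovery suites
therefore demonstrates correctness of the measurement chain under the
stated forward model, not robustness to every real-microscope artifact.

FRAP traces, paired-concentration tables (bivariate lognormal with
controlled log-scale correlation) and standard-curve tables come from the
same module, each seeded and bit-reproducible.

## Validation scales used by the test suite

The automated tests validate: CF against Monte-Carlo ball integration
(about 2 x 10^6 samples per diameter across 0.1–2.0 µm, 1% agreement);
noiseless PC recovery within 5% and noisy median error within 15% on the
d x PC design grid {0.4, 0.6, 0.8} µm x {5, 30, 130} with 50 seeds per
point; FRAP round trips to 1e-6 and a 60-replicate noise study for median
bias; exact Wilcoxon enumeration, a 5000-permutation Fligner null and a
dense eigensolver as statistical oracles; and 100-seed studies for the
randomized-pairing analyses. Single-cell stacks of roughly 110 x 107 x 19
voxels keep each simulated measurement around 0.2 s, so the full suite
runs in minutes on one CPU.

## Known limitations

* The correction assumes spherical P bodies and that all incremental
  fluorescence originates from the sphere; aspherical or clustered
  condensates bias CF.
* The FWHM first-crossing estimator is noise-biased narrow at low SNR;
  at the default photon budget the bias is negligible, but dim small
  objects (d near 0.4 µm at PC near 5) remain the least accurate corner.
* The chi-squared reference of the Fligner-Killeen test carries
  few-percent p-value error at n of order 20; the permutation oracle in
  the test suite quantifies it.
* Cell axis extents inherit the Otsu convention's sub-voxel bias; for
  morphometry-grade volumes a dedicated cell segmenter should replace
  `segment_cells()`.
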