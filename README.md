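# pbquant

Absolute quantification of proteins in membrane-less condensates from
confocal microscopy, built around the measurement problem posed by yeast
P bodies: the condensates (0.3–0.8 µm) sit at the microscope's resolution
limit, so the point spread function (PSF) dilutes their peak fluorescence
and naive intensity readings underestimate in-condensate concentrations by
up to an order of magnitude.

The package is aimed at cell biologists and microscopists who want
condensate inventories — concentrations, partition coefficients, molecule
counts, exchange kinetics — with the PSF effect corrected and every stage
testable against synthetic ground truth.

## What it computes

For a protein imaged in a GFP channel (optionally with an mCherry
condensate marker):

* **Dilution correction.** The PSF is an anisotropic Gaussian estimated
  from 0.2 µm bead stacks (`estimate_psf_from_beads()`). Convolving a
  uniform sphere of diameter d with it yields the correction factor CF(d),
  the fraction of true peak intensity that survives blurring
  (`build_correction_curve()`). Only the increment over the cytoplasm is
  diluted, so the true peak is
  `I_pbody = (I_measured − I_cyto) / CF + I_cyto`.
* **Segmentation.** Kapur MaxEntropy thresholding finds condensates, Otsu
  (with bright-tail suppression) finds cell boundaries; sizes are FWHM
  diameters, and objects smaller than 1.1× the lateral PSF FWHM are
  rejected as unmeasurable.
* **Calibration.** GFP standard curves (`fit_standard_curve()`) convert
  intensities to µM per acquisition setting; the partition coefficient is
  PC = C_pbody / C_cyto.
* **Sequestration.** Ellipsoidal cell volumes, a 0.67 cytoplasm fraction
  and Avogadro's number give molecule counts N_cyto and N_pbody, the
  sequestered fraction F_P = N_pbody/(N_cyto + N_pbody), its upper bound
  F_P,max (rescaled by the most sequestered reference protein), and the
  average cellular concentration.
* **Exchange kinetics.** FRAP/iFRAP traces are double-normalized and fit
  with I(t) = I∞ + (I0 − I∞)·e^(−kt); fractional recovery is
  F = (I∞ − I0)/(1 − I0), fractional decay F = I0 − I∞.
* **Co-partitioning statistics.** Pearson correlations of paired
  in-condensate concentrations, a randomized-pairing ratio null,
  Fligner-Killeen variance comparison, exact/midrank Wilcoxon rank-sum,
  and the HC/LC classification (PC ≥ 30 and C_pbody > 5 µM).
* **Network centrality.** Valency and eigenvector centrality (power
  iteration, spectrally shifted for bipartite safety) of the condensate
  interaction map, with complex collapsing (e.g. Lsm1–7 as one node).
* **Synthetic data.** `ground_truth()` / `generate_cell_stack()` render
  ellipsoidal cells with spherical condensates through the same optical
  model (PSF convolution before detector sampling, Poisson shot + Gaussian
  read noise), so the whole chain can be validated against known truth.

## Worked example

Simulate one cell with a 0.6 µm P body at 20 µM over a 0.2 µM cytoplasm
(true PC = 100), then run the full inventory:

```r
library(pbquant)

psf   <- psf_model(sigma_x = 0.13, sigma_z = 0.34)        # um
curve <- build_correction_curve(psf, seq(0.1, 2, by = 0.05),
                                voxel_size = c(0.05, 0.05, 0.2))
std   <- fit_standard_curve(
  generate_standard_curve_data(gain = 400, offset = 10,
                               concentrations = c(0, 0.5, 1, 5, 20)), "A")

truth <- ground_truth(
  cells   = data.frame(cx = 2.5, cy = 2.5, cz = 1.5, dx = 4.2, dy = 4.0,
                       dz = 2.8, c_cyto = 0.2),
  pbodies = data.frame(x = 1.8, y = 2.5, z = 1.5, d = 0.6,
                       c_pbody = 20, cell = 1),
  psf = psf, seed = 42)
sim <- generate_cell_stack(truth, voxel_size = c(0.05, 0.05, 0.2))

res <- run_inventory(sim, psf, std, correction = curve, seed = 1, trim = 0)
res$summary
#>   n_objects mean_pc sem_pc mean_C_pbody_uM sem_C_pbody_uM mean_C_cyto_uM
#> 1         1    99.8     NA            19.8             NA          0.198
#>   mean_f_p class
#> 1    0.397    HC
res$cells
#>   stack cell V_cell_um3 N_cyto N_pbody   f_p avg_conc_uM
#> 1     1    1       25.7   2056    1351 0.397       0.328
```

The recovered PC of 99.8 against a ground truth of 100 is what the
dilution correction buys: the raw peak reads ~48% of the true value at
this size. The cell holds ~2100 cytoplasmic and ~1350 sequestered
molecules, i.e. F_P ≈ 0.40 of the protein sits in the visible P body, and
the protein classifies as HC (highly concentrated).

Exchange kinetics from a noiseless trace at the experimental cadence
(5 s intervals, 150 s):

```r
kt    <- kinetic_ground_truth(k = 0.041, frac = 0.85, I0 = 0.2)
trace <- generate_frap_trace(kt)
fit_recovery(trace$t, normalize_frap(trace))
#> exponential fit: k = 0.041 /s, I0 = 0.2, Iinf = 0.88, F = 0.85 (converged)
```

See `vignettes/condensate-quantification.Rmd` for the model, the numerical
choices and the generator's scope.

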