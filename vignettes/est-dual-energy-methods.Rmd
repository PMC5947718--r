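---
title: "Equally sloped tomography and dual-energy elemental mapping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equally sloped tomography and dual-energy elemental mapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(esttomo)
```

## The measurement model

A scanning transmission X-ray microscope (STXM) records, pixel by pixel, the
intensity transmitted through a specimen. Under the Beer-Lambert law the
optical density `OD = -log(I / I0)` is the line integral of the linear
absorption coefficient `mu` (1/um) along the beam. Rotating the specimen
about a single axis (y here; the beam is z at zero tilt) gives a tilt series
of projections, and tomography recovers the 3D field `mu(x, y, z)`.

Two physical facts drive the pipeline:

* **Absorption edges.** Crossing a core-level binding energy of one element
  changes that element's mass attenuation `mu/rho` abruptly while every other
  constituent changes negligibly over a few eV. Two tomograms, just below and
  just above the edge, therefore differ only where the element sits, and the
  voxelwise difference `delta mu` converts into an element mass density via
  the jump `delta(mu/rho)`:
  `rho [g/cm^3] = 1e4 * delta_mu [1/um] / delta(mu/rho) [cm^2/g]`.
  No numeric value of the jump is baked into the package - it is a property
  of the element and edge in use, supplied through `edge_constants()`.

* **The missing wedge.** A flat specimen on a holder cannot be tilted to
  +-90 degrees; the unmeasured angular wedge (about 20 degrees here) makes
  plain filtered-backprojection-style inversion strongly anisotropic.

## Equally sloped tomography

The pseudo-polar grid evaluates the 2D discrete Fourier transform of an
`N x N` slice on `2N` line orientations whose *tangents* (not angles) are
equally spaced: a "basically horizontal" sector with `tan(theta) = 2l/N` and
a "basically vertical" sector with `cot(theta) = 2l/N`, each line carrying
`2N` radial samples (twofold radial oversampling). `ppfft2()` computes these
samples exactly (to floating tolerance) in `O(N^2 log N)` by a zero-padded
column FFT followed by a slope-dependent chirp-z (fractional FFT)
resampling. Its complex adjoint is `ppfft2_adjoint()`, and `ppfft2_inverse()`
solves the real-constrained least-squares inverse by conjugate gradients on
the normal equations, preconditioned by a radial density weighting
(weight `|k|`, DC weight 1/2) that compensates the oversampling of low
frequencies; full spectra invert to ~1e-10 relative error in about a dozen
iterations.

If projections are acquired exactly at the equally sloped angles
(`equally_sloped_angles()`), the Fourier slice theorem places the 1D
transform of each projection *exactly* on one pseudo-polar line - radial
spacing `sqrt(1 + s^2)/(2N)` cycles per pixel for line slope `s` - with no
interpolation. `projection_to_pp_line()` performs that fractional transform.
One bookkeeping subtlety is handled internally: BV-sector lines with
negative slope correspond to tilt angles wrapped from (90, 135) into
(-90, -45) degrees, so their detector axis runs opposite to the stored line
parameterization and the radial samples are taken at `-k`.

`est_slice()` then iterates between the two domains, per the classical
scheme: map measured projections onto their lines, start unmeasured lines at
zero; compute the least-squares inverse (warm-started CG; two inner
iterations per outer iteration, twelve on the cold start); push negative
density and density outside an optional support to zero; transform forward;
overwrite the measured Fourier coefficients - magnitude and phase, with no
relaxation - and leave the rest free. The normalized L1 distance between
calculated and measured coefficients is recorded as the error metric. The
default 300 iterations comfortably passes the point where the metric
stabilizes; with complete angular sampling the iteration reproduces the
direct inverse to ~1e-6, and with the ~21 degree wedge it beats zero-filled
direct inversion on essentially every slice (the acceptance suite requires
95%). Slices perpendicular to the tilt axis are independent and are batched
through one compiled call (`reconstruct_volume()`).

## The synthetic specimen

No experimental series ships with the package, so `default_cell_phantom()`
and `render_phantom()` build the study conditions synthetically: a flat
ellipsoidal macrophage-like cell (about 36 x 34 x 20% of the grid) with a
nucleus, 3-6 low-absorption vacuoles, at least twenty dense lysosomes with
diameters drawn from 200-400 nm, and 2-5 element-laden vesicles - alternating
uniformly filled interiors and 2-voxel peripheral rims, mimicking
nanoparticle aggregates at the vesicle membrane. Below-edge absorption values
(cytoplasm 0.35, nucleus 0.45, vacuoles 0.10, lysosomes 1.2 /um) sit in the
range of organelle soft-X-ray absorption coefficients; above-edge absorption
is *derived* from the assigned element density (1 g/cm^3) through the edge
constants, so quantification closes on the ground truth by construction.
Placement is rejection sampling with mild shrink-on-crowding; everything is
reproducible from one seed.

`simulate_tilt_series()` applies Beer-Lambert attenuation at a configurable
incident count (1e4 photons/pixel by default), optional Poisson counting,
and optional per-angle rigid misalignments drawn within a jitter bound and
applied identically at both energies (the stage drifts, not the optics; an
option decouples them). Two forward models exist on purpose:

* `model = "ray"` - rotation about y with bilinear interpolation and
  one-voxel integration steps: realistic and deliberately mismatched to the
  reconstruction operator;
* `model = "pp"` - the pseudo-polar-consistent model: per line, the
  length-`N` projection is the least-squares preimage of the slice's exact
  pseudo-polar samples under the fractional transform. Reconstruction from
  such data is near-exact, which is what oracle tests need.

The pp-consistent construction is exact only for slices representable by
integer-pitch detector samples, i.e. band-limited slices supported in the
inscribed disk. The renderer therefore applies an in-plane Gaussian band
limit (sigma 1.2 px by default, modelling the finite probe), implemented as
circular convolution with a normalized discrete Gaussian so that
nonnegativity and total absorption/element mass are preserved exactly. The
residual of the pp-consistent round trip falls from ~1e-3 of the line norm
for hard-edged slices to ~1e-7 at sigma 2.8 and below 1e-9 for pure Gaussian
mixtures; the exactness tests use correspondingly smooth phantoms. This is
the main respect in which passing tests understate real data: experimental
specimens are not band-limited, and the corresponding model error shows up
as the percent-level reconstruction error of the ray-model pipeline rather
than the 1e-6 of the oracle path. Real data also carry focus drift,
detector nonlinearity and dose-dependent shrinkage that the generator does
not emulate.

## Alignment

Before reconstruction the projections must share a tilt axis. The
centre-of-mass rule exploits two exact invariants of line integrals: the
mass centroid along the tilt axis is tilt-independent, and across it the
centroid of a rigid object follows `x_com(theta) = cx cos(theta) +
cz sin(theta)`. `com_align()` floors negative optical density at zero (a
noise guard), shifts every projection so its y centroid matches the series
mean and its x centroid lands on the rotation axis (the fitted sinusoid
re-centred at `cx = cz = 0`), using periodic Fourier phase ramps for
subpixel shifts - which requires free margins at the projection edges of at
least the jitter amplitude. Because interpolation perturbs the floored mass
slightly, the shift is iterated as a fixed point (at most six passes, each
re-shifting the original data once); a second call then changes nothing to
1e-8 px. The sinusoidal component of the jitter is mathematically
indistinguishable from a rigid object offset, so recovered shifts are
defined modulo that two-parameter family plus a common y offset; within that
convention recovery is exact for noiseless data and ~0.2 px RMS at 1e4
incident counts.

## Dual-energy mapping and quantification

The two reconstructed volumes are registered by whole-volume cross
correlation with subvoxel quadratic peak refinement (`register_volumes()`),
differenced (`diff_map()`; negative values retained - they carry the noise
floor), and thresholded on the intensity histogram
(`threshold_from_histogram()`). Otsu's criterion on 256 bins is the
reproducible stand-in for reading the histogram knee by eye; a percentile
override exists. Two deliberate design choices:

* **Element presence.** A specimen without the element still shows
  above-threshold voxels - the upper tail of reconstruction noise, which is
  spatially correlated and heteroscedastic (larger where the specimen is
  thick), so neither tail magnitude nor tail asymmetry separates reliably.
  What does is compactness: real element distributions are vesicle-shaped,
  noise excursions are scattered. The map is flagged element-free (empty
  mask) unless at least 20% of the thresholded voxels have half or more of
  their face neighbours in the mask; the measured interior fractions are
  0.09 for a null specimen at 1e4 incident counts against 0.33 (same noise,
  element present) and 0.99 (noiseless). An explicitly requested percentile
  is taken at face value.
* **Noise floor.** When noise dominates the histogram, Otsu's split can dip
  into the noise bulk (at 1e4 incident counts it lands near one sigma and
  would admit a fifth of the volume); the automatic threshold is therefore
  clipped from below at the median plus 4 MAD. Noiseless maps are
  unaffected (their floor is orders of magnitude under the Otsu value).
* **Mass vs localization.** At finite resolution a half-max-style threshold
  localizes the element well but clips the smooth skirts that carry part of
  its mass; `quantify()` therefore integrates over the mask grown by 3
  voxels (about 2.5 times the band-limit sigma), while the volume fraction
  uses the raw mask. The integral uses the signed difference, which is
  unbiased under zero-mean reconstruction noise; clipping negatives first
  would add the folded noise mean over the whole grown region. On the
  default phantom this closes the mass to a fraction of a percent where the
  undilated clipped integral loses ~18%.

The comparison target for the volume fraction applies the same histogram
rule to the noiseless ground-truth difference field, so that the check
measures reconstruction fidelity rather than the (resolution-dependent)
relation between a thresholded blurred shell and its crisp generator label.
`verify_threshold_projection()` closes the loop at projection level: the 3D
mask projected along the beam is compared (Dice) with a thresholded 2D
difference image, by default at an area-matched threshold so the score asks
purely whether the footprints coincide.

## Segmentation and reporting

`segment_by_mu()` partitions a reconstruction by user-supplied disjoint
absorption intervals (a histogram-based helper proposes candidates);
`component_stats()` extracts 26-connected components, discarding those under
3 voxels, and reports volumes, equivalent spherical diameters, centroids,
mean absorption difference and the *rim fraction* - the share of a
component's element voxels in its 2-voxel outer shell. Note the geometric
floor of that statistic: a uniformly filled sphere of radius `r` voxels has
rim fraction `1 - ((r-2)/r)^3`, so the filled-vs-rim contrast (< 0.5 vs
> 0.8) is meaningful for components of radius about 10 voxels and up.
`classify_vesicles()` applies configurable size/rim cutpoints to type
components along the observed progression from small dense filled vesicles
to large low-density vesicles with membrane-bound element.
`pipeline_report()` serializes all stage results to schema-tagged JSON at
full precision.

Expert identification of organelles from morphology is not automated; the
class intervals and the morphology statistics are the only proxies.

## Diagnostics

`rfactor_projections()` re-projects the reconstruction with the ray model
and compares against the measured series (`sum|calc - meas| / sum|meas|` per
angle); on the realistic noiseless pipeline the mean sits near 0.5%. Note
that this diagnostic is meaningful against physically parameterized
projections; against the least-squares pp-consistent sinogram it mostly
measures that parameterization's oscillation at steep slopes.
`fsc_resolution()` correlates two volumes per spatial-frequency shell - by
convention reconstructions from the even and odd angle subsets - and reports
the first crossing of 0.5 (the package's criterion; identical volumes report
the two-voxel Nyquist length). `damage_check()` registers two same-angle
projections by their centroids and reports their normalized L1 discrepancy,
the radiation-damage control.

## Numerical choices and problem sizes

Degenerate inputs are defined, not special-cased: all-zero sinograms
reconstruct to zero with a zero error history; an all-zero measured spectrum
makes the error metric 0 by convention; empty masks quantify to zero mass
and fraction; two empty footprints have Dice 1. Poisson zeros are clamped to
one count before the logarithm (with a message). Intensity series must carry
their incident counts; conversion failures are errors, not guesses.

The compiled core batches all slices of a volume through a handful of
column-wise FFTs (FFTW), and exploits the conjugate symmetry of spectra of
real slices wherever the data flow guarantees it; the public adjoint takes
the general path so the adjoint identity holds for arbitrary complex
spectra. Tests and the acceptance script run the full study geometry at
64^3 (about 75 s per 300-iteration volume on one core); the phantom
occupies ~43 of 64 slices and rows without signal are skipped. The same
code paths serve larger grids unchanged.

The pseudo-polar grid size needed to reproduce the experiment's exact
46-angle count is not determinable from the available description (no even
`N` yields exactly 46 equally sloped angles within +-79.4 degrees); the
package exposes `N`, reports the achieved count, and uses `N = 64` - 117 of
128 lines measured, the same ~91% angular coverage and ~21 degree wedge as
the experiment.
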