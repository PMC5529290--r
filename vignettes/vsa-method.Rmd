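---
title: "Measuring sub-diffraction t-tubule diameter with the dual-dye V:SA method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring sub-diffraction t-tubule diameter with the dual-dye V:SA method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TubuleVSA)
```

## The measurement problem

Transverse-axial tubules (TTs) of cardiac ventricular myocytes are
sarcolemmal invaginations typically 100–400 nm across — below the
diffraction limit of a confocal microscope, whose point spread function
(PSF) has a full width at half maximum (FWHM) of roughly 0.25 µm laterally
and 0.6 µm axially. A tubule's apparent width in an image therefore says
little about its true diameter. What blurring cannot destroy, however, is
integrated signal: convolution conserves mass. If the tubule lumen is
filled with an extracellular volume dye (e.g. calcein) and the tubule wall
carries a membrane dye (e.g. FM4-64), the local ratio of volume signal to
membrane signal — the volume-to-surface-area ratio, V:SA — grows linearly
with tubule diameter for a fixed cross-sectional shape, and can be
calibrated to physical units with a geometric model.

## The model

Normalize the volume channel so the perfusion bath reads 1 (it is pure
extracellular dye) and the membrane channel so the surface sarcolemma (SS)
reads 1 (it is a reference membrane of known, planar geometry). For a
cylindrical tubule of diameter $D$ imaged with a *spherically symmetric*
Gaussian PSF of width $\sigma$ (FWHM $= 2\sqrt{2\ln 2}\,\sigma$), the
channel ratio evaluated on the tubule axis is, in the sub-resolution limit,

$$
V\!:\!SA \;=\; \frac{A/(2\pi\sigma^2)}{P/(\sigma\sqrt{2\pi})}
\;=\; \frac{D/4}{\sigma\sqrt{2\pi}}
\;=\; \frac{D}{2\,\mathrm{FWHM}}\sqrt{\frac{\ln 2}{\pi}},
$$

where $A = \pi D^2/4$ is the lumen area and $P = \pi D$ the wall perimeter
per unit length; the numerator is the blurred peak of a thin filled disc,
the denominator the blurred peak of a thin ring divided by the blurred peak
of the reference plane ($1/(\sigma\sqrt{2\pi})$ per unit surface density).
Diameter is recovered by the linear inversion implemented in
`vsaToDiameter()`; the slope $\sqrt{\ln 2/\pi}/(2\,\mathrm{FWHM})$
(`modelSlope()`) evaluates to 0.39 µm⁻¹ at FWHM 0.6015 µm. At the SS itself
the volume channel is a blurred half-space step, which reads exactly 0.5 at
the membrane plane — a built-in calibration check exercised by
`renderHalfspaceCalibration()`.

The same relation holds *exactly, for any diameter*, if both channels are
integrated over the tubule's blurred neighborhood instead of sampled at the
skeleton (mass conservation; see `integratedVSA()` and the accuracy section
below).

## Why the PSF must be symmetrized first

A confocal PSF is anisotropic (worse axially). The peak signal of a blurred
tubule then depends on the tubule's orientation relative to the optical
axis, which would masquerade as a diameter difference. The method therefore
blurs the data laterally until the effective PSF is spherical with FWHM
equal to the raw axial FWHM: `symmetrizationBlur()` returns the per-axis
extra Gaussian widths $\sigma_{extra} = \sqrt{\sigma_z^2 - \sigma_{xy}^2}$
(zero along z), and `symmetrizePSF()` the resulting isotropic PSF. The
package assumes z is the worst axis and refuses to run otherwise. The raw
PSF is estimated from a bead stack (`measurePSF()`): per-axis Gaussian fits
through the bead centroid, corrected for the finite bead size by quadrature
subtraction of the sphere's equivalent Gaussian width ($\sigma_{bead}^2 =
R^2/5$, the per-axis variance of a uniform ball).

## Processing pipeline

`runPipeline()` chains the stages in a fixed order:

1. **Masks** (`buildMaskSet()`). All masks are derived from PSF-symmetrized
   copies of the channels, so that skeleton placement is
   orientation-independent and marks tubule *axes* (with the raw PSF,
   lateral resolution can split a wide tubule into two walls and the
   skeleton would trace a wall). The cell mask is the below-threshold
   (dye-free) region of the volume channel after morphological closing
   (absorbing sub-resolution lumina) and largest-component selection; the
   bath is the far above-threshold region. The SS voxel set is the cell
   border restricted to in-focus, valid-reference regions: gradient
   cutoffs and a 60° normal cone about the focal plane reject the
   out-of-focus top/bottom caps; voxels are snapped to the
   membrane-intensity maximum along the local normal, so the SS reference
   samples the membrane plane's true peak (a one-voxel, 60 nm offset would
   already bias the 0.5 calibration point to 0.45); the volume signal at
   the snapped voxel must sit at the half-space mid-step (0.5 ± 0.15 of
   the bath level), which is the regime where the SS calibration is
   meaningful; and a recession test drops voxels lying more than 0.1 µm
   behind any neighbor (within a 0.9 µm window, about half a sarcomere
   period) along the local outward normal — z-groove invagination mouths
   are recessed behind the surrounding crests, the true surface plane is
   recessed behind nothing. The TT mask thresholds
   the membrane channel *within the eroded cell interior* (Otsu), floored
   at 20% of the SS membrane signal so a tubule-free cell yields an empty
   skeleton; `skeletonize3D()` thins it to single-voxel lines
   (topology-preserving simple-point peeling, 26/6-connectivity, curve
   endpoints kept, hence idempotent), and the TT skeleton is the part
   inside the cell eroded by one FWHM, minus the SS, with short spurs
   pruned.
2. **Background** (`estimateBackground()`, `subtractBackground()`). The
   cytosol — the cell minus the blurred neighborhoods of the TT skeleton
   *and of the SS* — provides the dye-free background: median-smoothed in
   place, nearest-neighbor interpolated (physical distance, deterministic
   lowest-z/y/x tie-break) onto the remaining cell voxels, zero outside the
   cell. Excluding the SS neighborhood from the background source matters:
   otherwise the background model absorbs the surface membrane signal and
   subtracting it destroys the SS normalization reference. Negative values
   after subtraction are kept until the final ratio (clipping earlier would
   bias the post-blur averages upward).
3. **Symmetrization** (`applyBlur()`): the extra lateral blur, after
   background subtraction, before normalization.
4. **Normalization** (`normalizePair()`): volume channel divided by the
   trimmed mean (central 80%) over the bath mask; membrane channel by the
   trimmed mean over the SS voxels. Any channel gain cancels exactly —
   downstream diameters are invariant to dye concentration and detector
   efficiency, which is the method's point.
5. **V:SA map** (`computeVSA()`): the channel ratio at TT-skeleton voxels;
   voxels with membrane signal below 10% of the SS reference are dropped
   and counted (division guard). Diameters follow by the linear model with
   the symmetrized FWHM; `summarizeCell()` reports mean, SD, SEM, n and a
   histogram (default bin 0.01).
6. **Network geometry**: skeleton length from the physical-weight minimum
   spanning tree of the 26-adjacency skeleton graph (exact for tree-shaped
   skeletons; anisotropy-aware edge lengths), divided by cell volume;
   per-voxel orientation from the principal eigenvector of the local
   structure tensor (0.5 µm window), measured from the transverse plane;
   transverse/axial classes are the closed ±15° intervals; and the derived
   quantities area density $\pi D L$, volume fraction $\tfrac{\pi}{4}D^2 L$
   and membrane fraction (`derivedGeometry()`).

Cable properties (`membraneResistivity()`, `lambdaDC()`, `lambdaAC()`,
`detubulationExtrapolation()`) translate the diameters into electrical
length scales: $\lambda_{dc} = \sqrt{D R_m/(4 R_L)}$, and under sinusoidal
drive $\lambda_f = \lambda_{dc}/\mathrm{Re}\sqrt{1 + i\,2\pi f \tau_m}$.
The real-part reading of the ac form is the default because at 150 Hz and
$\tau_m = 7$ ms it gives the expected ~50% reduction (the modulus reading,
also selectable, gives ~61%).

## The phantom: what it emulates, and what it does not

`renderPhantom()` forward-simulates the imaging experiment so every stage
can be validated against known ground truth without any real data: a
half-space cell (optionally with sinusoidal z-groove corrugation) bathed in
volume dye, tubules as cylinders or elliptical cylinders along arbitrary
polylines, a membrane rendered as a true *area density* (shells normalized
so thickness cannot leak into V:SA), anisotropic Gaussian blur, and
optional Gaussian or Poisson noise applied after blurring, seeded and
bit-reproducible. Defaults mirror the acquisition geometry the method was
designed for: 60 nm lateral / 180 nm axial voxels and a raw PSF of
0.25/0.25/0.60 µm FWHM. Dye amplitudes and noise levels are free
parameters (unit bath amplitude, unit surface density, no noise by
default); no published values constrain them, and the normalization makes
the defaults immaterial.

Numerical care in the renderer turned out to be essential at these scales,
and the choices are worth recording. Rasterization is anti-aliased by
signed radial distance on a supersampled grid, and first moments are pinned
to the analytic geometry (a 100 nm lumen naively voxelized at 60/180 nm can
lose 16% of its volume to alignment). Rendering happens on an internal
grid refined to the finest voxel pitch and is box-averaged down only after
blurring — blurring after rasterization onto the anisotropic acquisition
grid would apply the detector box twice along z and misquote thin
structures by several percent. Convolution kernels are bin-integrated
Gaussians truncated at 4σ with edge-replication padding (half-space scenes
keep their asymptotic values). With these in place the rendered blurred
fields match a closed-form oracle (ring/disc × Gaussian in terms of Bessel
functions, detector-box averaged) to about 1% per channel.

The phantom does *not* model Airy-disc or Airyscan optics, refractive-index
aberrations, spatially varying PSFs, dye diffusion kinetics, bleaching,
motion, or channel crosstalk. Passing its tests therefore demonstrates the
correctness of the *image-processing chain and the geometric calibration*,
not robustness to every optical artifact of a real microscope.

## Accuracy of the linear conversion

The linear model is the small-diameter limit of the exact blurred-cylinder
solution. Evaluating the exact fields at the tubule axis gives

$$
\frac{V\!:\!SA_{peak}}{V\!:\!SA_{linear}} = \frac{e^{x}-1}{x},
\qquad x = \frac{R^2}{2\sigma^2},
$$

so peak-sampled V:SA overshoots the linear calibration as $D$ approaches
the FWHM: by about +1% at $D=0.1$ µm, +3% at 0.17, +6% at 0.25, +9% at
0.30, +13% at 0.36 and +27% at 0.50 µm for FWHM 0.6 µm. The full pipeline
on phantoms reproduces this curve to a few tenths of a percent, and the
same numbers set the accuracy statement for real use: with peak sampling,
recovered diameters are within 10% of truth for $D \lesssim$ FWHM/2, and
biased upward beyond that. Group *comparisons* (e.g. between species)
remain valid throughout because the mapping is strictly monotone. Where
absolute accuracy at larger diameters matters, `integratedVSA()` integrates
both channels over the tubule neighborhood and is exactly linear at all
diameters (verified within 5% across 0.1–0.5 µm in the test suite), at the
cost of mixing neighboring tubules in dense networks. After
symmetrization, recovered diameters for the same tubule oriented along the
optical axis versus in the focal plane agree to ~0.3%; before it they
disagree by tens of percent, which is the reason the symmetrization step
exists.

For elliptical cross-sections (E = minor/major), V:SA decreases slightly at
fixed width; `ellipseEquivalentAxes()` reports the ellipse with the same
area-to-perimeter ratio as the circular-model diameter (closed form via the
complete elliptic integral of the second kind). At E = 0.75 a circular
0.356 µm estimate corresponds to ~0.417/0.313 µm axes; published values
for this conversion (0.40/0.32 µm) agree to ~4%, the residual reflecting an
unspecified upstream rounding, so both are quoted where relevant.

## Numerical and design choices

* Axis order is (z, y, x) everywhere, voxel centers at (index − ½)·pitch,
  all physical quantities in µm; one stated convention prevents half-voxel
  bugs.
* FWHM ↔ σ uses $2\sqrt{2\ln2}$, defined once (`fwhmToSigma()`).
* Otsu thresholds use 256 bins over the observed range; the threshold
  reports a separability attribute. Degenerate (constant) inputs are
  errors, not silent guesses.
* Morphology uses separable box elements with physical half-widths
  (anisotropy-aware); erosion treats out-of-grid as foreground so cells
  flush with the field of view are not eroded from that side.
* Nearest-neighbor ties break deterministically (lowest z, then y, then x).
* The skeleton-length MST estimator is exact for trees; cycles (rare after
  thinning) are undercounted by the length of one chord per loop.
* Test problem sizes: most scenes are 48×128×144 voxels (z,y,x) or
  smaller with 6–7 µm tubules — large enough that bath, SS and tubule
  regions are separated by several FWHM, small enough to keep the full
  suite fast.
* Group statistics: Mann-Whitney exact for n ≤ 8 without ties, otherwise
  normal approximation with tie correction; variance ratio by F test;
  Spearman with mid-ranked ties.

## Known limitations

The method reports a shape-conditional size: it cannot distinguish two
closely apposed thin tubules from one flattened wide one, and a strongly
elliptical tubule read with the circular model is reported as an
equivalent-V:SA circle. Peak-sampled diameters saturate above ~FWHM/2 as
quantified above. Segmentation quality bounds everything downstream: the
TT skeleton must actually trace tubule axes, which the mask-construction
rules above ensure on phantoms but which very low signal-to-noise real data
could defeat. Analysis is single-cell per stack (largest component); no
registration, crosstalk unmixing, or time series support.
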