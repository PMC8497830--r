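---
title: "Models and methods behind mlsfm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mlsfm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlsfm)
```

## The problem

Whole-brain fluorescence imaging of cleared mouse brains faces a
three-way trade-off between resolution, speed, and data volume. Imaging
an entire brain at sub-micron voxels takes days and produces tens of
terabytes, yet sparsely labeled neurons occupy only a small fraction of
the tissue. Multi-scale light-sheet fluorescence microscopy (mLSFM)
resolves the trade-off by decoupling detection from illumination: a fast
low-magnification pass detects where signal is, and only those tiles are
re-imaged at high magnification. `mlsfm` is a desk-scale simulator of
that computational pipeline -- optics, phantoms, acquisition, triage,
stitching, point-spread-function (PSF) characterization, and
electrode-boundary localization -- with every stage testable against
ground truth.

## Optical model

Light-sheet microscopy illuminates a plane orthogonal to the detection
axis, so image brightness scales with the light-gathering power of the
detection objective over the image area,

$$B_\mathrm{LSFM} \propto \frac{\mathrm{NA}^2}{\mathrm{Mag}^2},$$

whereas wide-field epifluorescence both condenses excitation and gathers
emission through one objective, $B_\mathrm{WF} \propto
\mathrm{NA}^4/\mathrm{Mag}^2$. Because NA grows concavely with
magnification across commercial objective lines (the packaged synthetic
table `objective_na_table()` emulates this), the light-sheet law is
maximized at the *lowest* magnification while the wide-field law peaks at
an interior magnification -- the reason a zoomable light-sheet detection
path can trade magnification for brightness freely. Both laws carry
proportionality constant 1 here; absolute photon budgets live in the
acquisition simulator.

The detection chain is a macro objective (2x, NA 0.5) behind a 0.63--6.3x
zoom body and a 6.5 um-pitch sCMOS sensor, so total magnification spans
1.26--12.6x and the effective pixel size is `pitch / Mag` (0.52 um at
full zoom). Lateral resolution uses the Rayleigh criterion
$0.61\lambda/\mathrm{NA}$; the default emission wavelength is 0.52 um
(EGFP/EYFP band), giving 0.63 um at NA 0.5.

The illumination sheet is a cylindrical Gaussian beam: half-thickness
$w(z) = w_0\sqrt{1+(z/z_R)^2}$ with $z_R = \pi w_0^2 n/\lambda$. The
intensity profile across the sheet is Gaussian with $\sigma = w/2$, so a
1.7 um waist gives a 2 um intensity FWHM. Trimming the illumination
aperture widens the waist as $w_0 = \lambda/(\pi a \mathrm{NA})$; the
instrument uses this to match sheet thickness to the field of view, and
the simulated pipeline does the same -- the low-magnification passes use
a deliberately opened-up sheet (default $w_0 = 12$ um) matched to their
20 um z-spacing, while the high-resolution pass uses the thin 1.7 um
waist.

## Synthetic phantoms

The phantom generator produces what the pipeline needs to be tested
against truth, not biophysically realistic anatomy:

* **Neurons** grow as discrete-step random walks (default 8 um steps)
  from uniformly placed somata, with direction persistence, per-step
  bifurcation probability, and reflection at the volume faces. This
  gives single-rooted acyclic trees whose total cable length correlates
  linearly with branch count, written and read in standard SWC format.
* **Two SNR classes.** A configurable fraction of neurons (default 1/3)
  is "dim", emulating the non-uniform brightness of viral labeling. The
  default bright and dim intensity levels were calibrated once, by
  simulating a single axon under the default detection-pass settings, so
  that a bright axon at the waist plane measures a subregion
  signal-to-noise ratio (SNR) near 34.5 and a dim one near 4.5. Within a
  full tile the per-tile maximum across subregions typically exceeds the
  single-axon figure, because tortuous axons overlap themselves and
  branch.
* **Background** is a uniform photon level plus a smooth autofluorescence
  texture (a Gaussian-smoothed bilinear field, default SD 900 photon
  counts at detection-pass scaling, 120 um correlation length),
  replicated along z so a z-projection preserves it. This texture is
  load-bearing: real cleared tissue is texture-dominated, and the
  published 2 SD / 0.5 SD triage thresholds only separate sparse signal
  from empty tissue when the background SD (texture) comfortably exceeds
  the shot-noise extremes of a subregion. Blood-vessel-like bright tubes
  are available but off by default.
* **Bead fields** are sub-resolution point emitters splatted by
  trilinear weights (sub-voxel positions preserved); counts are Poisson
  in the requested density. **Dye pools** are exactly uniform.
* **Electrode tracks** are labeled units at uniform distances from a
  boundary with narrow-spiking probability
  $1/(1+e^{-(d-d_0)/s})$, the generative twin of the logistic fit.

All generators are pure functions of (config, seed); a single pipeline
seed is expanded into named per-module streams (`substream_seed()`) so
stage order never perturbs results.

What the phantom does **not** emulate: light scattering and depth
dependent attenuation, refractive-index mismatch aberrations, stripe
artifacts, clearing-induced deformation, or realistic per-cell-type
morphology. Tests passing on the phantom therefore validate the
pipeline's logic and calibration behavior, not its robustness to those
real-data effects.

## Forward acquisition model

`simulate_stack()` renders one tile stack per call:

1. **Axial (sheet) blur.** Each output plane integrates the phantom
   along z with a Gaussian kernel whose sigma is half the local sheet
   thickness, convolved analytically with a box of the motion-blur
   length $v\,t_\mathrm{exp}$ (the stage moves continuously along z). In
   `stationary` mode the sheet waist lies on the line through the tile
   center and thickness grows with each image row's lateral distance
   from it; in `tiled` mode (the axially swept sheet synchronized with
   the rolling shutter) every row sees waist thickness. Kernels are
   renormalized per plane, so a uniform dye pool keeps its level, and an
   out-of-focus bead spreads over more planes and dims -- both the
   behaviors the mode comparison tests assert.
2. **Lateral blur** by an isotropic Gaussian PSF at the Rayleigh FWHM,
   then bilinear sampling at the effective pixel size.
3. **Brightness and camera.** Expected photons scale with
   $\mathrm{NA}^2/\mathrm{Mag}^2$ and exposure; counts are Poisson shot
   noise plus Gaussian read noise plus a constant offset (gain 1
   count/photon by default), rounded and clamped to 16 bits. A
   `shot_noise = FALSE` switch yields deterministic expectation images
   for calibration measurements.

Idealizations, stated: perfect rolling-shutter synchronization (no TTL
latency), no photobleaching, no stage positioning error, and motion blur
as a box kernel -- at the default 0.08 mm/s and 30--50 ms exposures the
blur length (2.4--4 um) is comparable to the coarse z-steps, matching
the instrument's argument that continuous scanning adds no evident blur.

## Planning and cost

Mosaics place fields of view at stride $(1-v)F$ with the final tile
pinned to the far edge; the per-axis count is
$\lceil (W-F)/((1-v)F)\rceil + 1$. Sectioning advances by $D - o$ per
cut (imaged depth minus the 100 um overlap slice), giving
$1 + \lceil (L-D)/(D-o)\rceil$ sections. The z overlap between stacks
is a fraction of stack depth rounded to whole z-steps; a fixed-distance
parameterization is available through `section_overlap_um` since thick
sections quote 100--300 um overlaps. The cost model counts frames,
16-bit bytes, exposure and stage time (from the TTL trigger schedule:
period = pulse interval / stage speed) and charges a constant per
vibratome cut, defaulted at 180 s so a ten-cut run spends half an hour
sectioning. Wall-clock predictions are reported, never asserted.

## Tile triage

Each detection-pass tile is reduced to its z maximum-intensity
projection (MIP), split into a 4 x 4 grid of windows overlapping by 10%,
and classified three ways:

* **Background** = grayscale morphological opening of the MIP with a
  disc (the rolling-ball estimate; default radius a quarter of the
  window width). The opening engine is an exact shift-and-min/max
  implementation whose border convention is explicit (out-of-image
  pixels do not participate), verified against a brute-force per-pixel
  oracle.
* **Statistic** = a high percentile (99.9th by default; plain max
  available) of the background-subtracted window, referenced back to the
  background level so thresholds read on the raw intensity scale. The
  percentile is robust to isolated hot pixels.
* **Background mean and SD** are the median and scaled MAD of the *raw*
  MIP, estimated once per tile. Two design points deserve explanation.
  First, robust location/scale: sparse axons barely move a median/MAD.
  Second, tile-level rather than per-window estimation: the texture
  correlation length is comparable to a window, so per-window MADs are
  unstable (a locally flat window collapses the SD and inflates its
  SNR), while the full tile spans several correlation lengths. With SD
  estimated on the residual instead, any extreme-percentile statistic of
  pure noise sits at a fixed ~3 SD and every empty tile would classify
  as signal -- the texture-referenced SD is what makes the 2 SD / 0.5 SD
  thresholds meaningful.
* **Border band.** The opening cannot see past the image border, so the
  background is unreliable within one disc radius of the edge; that band
  is excluded from the statistic, and ground-truth tile occupancy is
  attributed to the same interior region. The 5% mosaic overlap means
  structures at a seam reappear near the neighbouring tile's border.

A window is `signal` above $\mu + 2\sigma$, `no_signal` below
$\mu + 0.5\sigma$, `uncertain` between. Uncertain windows stand in for
the manual review step; the default rescan policy
(`signal_or_uncertain`) is conservative, favoring low false negatives.
False-positive rate is quoted over rescanned tiles and false-negative
rate over all tiles, each matching how such rates are conventionally
printed; both definitions are implemented side by side in
`evaluate_detection()`.

On the default phantom this machinery reproduces the qualitative
behavior the design targets: bright-class tiles are never missed, any
miss is dim-class, and a minority of empty tiles land in `uncertain`
(occasionally `signal` when a soma sits just outside a tile's attributed
region and shines in), producing a nonzero false-positive rate of the
same order as real multi-scale runs.

## Stitching, downsampling, boundary distance

Pairwise tile shifts come from phase correlation of the nominal overlap
crops (integer-valued by default; parabolic sub-pixel refinement is off
because real tile shifts are ~10 px integer-scale). Global positions
propagate over a spanning tree with cycle-closure checks; fusion blends
overlaps with border-distance weights normalized to one, so tiles cut
from one volume reconstruct it exactly. Non-rigid z stitching is out of
scope -- a documented limitation. Downsampling for atlas-registration
hand-off is block-mean pooling (10 or 25 um voxels in practice);
registration itself is delegated to external tools, and the registration
quality metric provided is the symmetrized mean nearest-neighbour
distance between boundary point sets, whose translated-circle analytic
value $2t/\pi$ anchors its tests.

## PSF characterization

Beads are local maxima above a robust threshold; any pair closer than
the minimum separation is rejected outright (overlapping profiles bias
fits). Per-bead crops are mean-projected onto each axis -- projection of
a Gaussian preserves its width along the kept axis -- and fitted with a
four-parameter Gaussian (amplitude, center, sigma, baseline; the
baseline absorbs the camera offset) by Levenberg--Marquardt least
squares; FWHM $= 2\sqrt{2\ln 2}\,\sigma$. Aggregation across beads is
the median. Axial profiles are taken at the stack's z-step without
interpolation, so an axial estimate close to twice the step size is
sampling-limited -- a caveat reported, not asserted. Sampling broadens
and never narrows a Gaussian, a property the tests sweep over sub-pixel
shifts.

## Electrode-boundary localization

Narrow/wide spike labels are inputs (spike sorting and waveform
classification are upstream of this package). The boundary estimate is
the half-probability point $d_0$ of a Bernoulli maximum-likelihood
logistic fit on raw unit labels -- bin-free, unlike least squares on
binned fractions -- with a profile-likelihood confidence interval
obtained by refitting the scale at fixed $d_0$. Perfectly separated
data leave $d_0$ in the gap between classes; single-class data are
rejected as non-identifiable. Both pooled and per-track fits are
available since multi-track data are naturally hierarchical.

## Problem sizes and numerical choices

The default demo runs at desk scale, chosen so the full pipeline and its
tests execute in well under a minute each on one CPU: a 1 x 1 x 0.04 mm
phantom at 2 um voxels, a simulated 128 px sensor (pixel size is
unaffected; the sensor is simply cropped), a 4 x 4 detection-pass
mosaic, and a 40-frame-per-tile high-resolution pass. All planners
accept arbitrary extents. Other numerical choices: Gaussian kernels
truncated at 4 sigma with renormalized borders; splat amplitudes along
polylines normalized so the drawn line's peak equals the configured
level; phase-correlation spectra floored at machine epsilon; Gaussian
fits started from the discrete peak and half-maximum crossing width; and
ties in the correlation peak broken by first index.

## Known limitations

* The forward model is geometric-optics plus Gaussian PSF; no
  diffraction integral, aberrations, scattering, or depth dependence.
* Triage calibration assumes texture-dominated background; on
  texture-free data (e.g. beads in agarose) the percentile statistic
  flags noise extremes, so triage is meant for tissue-like fields.
* Rigid integer stitching only; non-rigid z-matching is not modeled.
* The sectioning scheduler assumes constant imaged depth per section.
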