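# mlsfm

Desk-scale simulation and planning toolkit for **multi-scale light-sheet
fluorescence microscopy (mLSFM)** of cleared whole brains.

Whole-brain imaging at sub-micron voxels is slow and produces terabytes,
yet sparsely labeled neurons occupy only a small fraction of the tissue.
Light-sheet microscopy decouples illumination from detection, so image
brightness follows

&nbsp;&nbsp;&nbsp;&nbsp;*B* ∝ NA² / Mag²

(versus NA⁴ / Mag² in wide-field), which makes low-magnification
light-sheet images *bright* — bright enough to detect where the signal
is, and to re-image only those tiles at high magnification. `mlsfm`
implements the computational core of such a system against synthetic
phantoms with known ground truth:

- **optics** — brightness laws, magnification chain, effective pixel
  size, Rayleigh resolution, Gaussian sheet geometry
  (waist/Rayleigh-range/aperture control), telescope expansion;
- **phantom** — seeded generators: branching neuron trees (SWC in/out)
  in bright and dim labeling classes, sub-resolution bead fields, dye
  pools, autofluorescence texture, electrode-track spike-width data;
- **acquisition** — mosaic / z-stack / sectioning planners with
  frame-byte-time cost accounting, and a forward imaging simulator
  (stationary vs. axially swept "tiled" sheet, motion blur, Poisson +
  read-noise camera);
- **triage** — z-MIP, rolling-ball (grayscale opening) background,
  overlapping 4×4 subregions, dual-threshold three-way classification,
  rescan selection, false-positive/negative evaluation;
- **stitch** — phase-correlation offsets, spanning-tree globalization,
  blended fusion, block-mean downsampling, boundary-distance metric;
- **psf** — bead detection and per-axis Gaussian FWHM fitting;
- **electrode** — logistic (Bernoulli ML) fit of the narrow-spiking
  fraction along a track; the half-probability distance estimates the
  boundary location.

## Worked example

```r
library(mlsfm)

# instrument constants from the detection chain
effective_pixel_size(6.5, total_magnification(6.3, 2))  # 0.515873
rayleigh_resolution(0.52, 0.5)                          # 0.6344
sheet_fwhm(sheet_model(1.7))                            # 2.001597

# full multi-scale run on the default phantom
man <- run_pipeline(pipeline_config(acquire_pass2 = FALSE), seed = 1)
man
#> <run_manifest> seed 1; 16 pass-1 tiles, 7 flagged; fp 0.000 fn 0.000
man$frame_counts
#> $pass2_planned
#> [1] 3500
#> $pass2_full_coverage
#> [1] 8000

# electrode-boundary localization from spike-width labels
fit_sigmoid(generate_spike_track(d0_um = 22, slope_um = 10,
                                 n = 2000, seed = 1))
#> <sigmoid_fit> d0 = 20.94 um (95% CI 17.14..24.73), slope = 11.86 um, n = 2000
```

Reading the output: the detection pass covered the phantom with 16
tiles, triage flagged 7 of them (exactly the tiles that truly hold
neurons at this seed — zero false positives and zero false negatives),
so the high-magnification pass needs 3500 frames instead of the 8000 a
full-coverage scan would take. The logistic fit recovers the generator's
22 µm half-probability boundary distance within its confidence
interval.

A thin command-line front end over the same functions ships in
`inst/cli/mlsfm.R` (`run`, `phantom`, `plan`, `triage`, `psf`,
`boundary-fit` subcommands).

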