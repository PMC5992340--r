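# eisoclem

Correlative cryo-microscopy registration and membrane-coat morphometry.

Eisosomes are furrow-like invaginations of the yeast plasma membrane
scaffolded by the BAR-domain proteins Pil1/Lsp1. Locating them inside
frozen cell sections and deciding whether their membrane carries a protein
coat requires a chain of quantitative steps: registering fluorescence
coordinates into electron-microscopy maps via fiducial beads, screening
section areas by focal-plane attachment, acquiring tilt series with a
grouped dose-symmetric scheme, extracting sub-volumes along clicked
membrane profiles, collapsing and class-averaging them, and finally
measuring membrane thickness and coat curvature. `eisoclem` implements
that chain as a tested R package, together with a synthetic-phantom module
(fiducial scenes, focal stacks, membrane tomograms with furrows, coats,
noise and a missing wedge — all with known ground truth) so every stage is
verifiable end to end without microscope data.

## The core quantities

- **FM→EM registration.** Least squares over bead pairs,
  `min_{A,t} Σ_i ‖e_i − (A f_i + t)‖²`, affine by default (similarity
  optional), with a leave-one-out estimate of the prediction error at the
  target spot.
- **Grouped dose-symmetric tilt scheme.** ±60° in 1° steps, groups of four
  per side starting at 0°, uniform split of a 110 e⁻/Å² total dose.
- **Membrane thickness.** From the band profile `p(y)` (mean of the
  central 7 pixel columns of a class average): threshold
  `(max p + dip)/2` where `dip` is the deepest extracellular local
  minimum; thickness is the width of the contiguous ≥-threshold interval
  containing the peak, in nm. Relative membrane thickness divides an
  eisosome's value by its paired plasma-membrane patch: ≈1 means bare
  membrane, >1 an added coat.
- **Coat curvature.** Least-squares circle (algebraic seed + geometric
  refinement) through points along the densest coat arc; diameter in nm.
- **Cohort comparison.** Two-tailed Welch test (unpooled variances,
  Satterthwaite df) of shallow vs curved relative thickness.

## Worked example

The `analysis/` directory holds the numbered workflow
(`01_simulate_phantoms.R` … `06_morphometry.R`); each script is a thin
driver over the package and writes its tables under `results/`. Running
them in order prints, among other things:

```
$ Rscript analysis/02_registration.R
<fitted_transform> affine, rms residual 1.714 EM px
target predicted at EM (375.84, 286.77); true (376.57, 286.42); LOO error 2.848 px
delta-z of the detached signal: 3.60 um
```

With 0.5 px bead-localization noise mapped through a ~2× magnification
change, a ~1.7 px rms residual is the expected noise floor; the predicted
target lands 0.8 px from its true position, inside the leave-one-out
estimate, and the detached test emitter is rejected by the 1 µm
attachment threshold.

```
$ Rscript analysis/03_tilt_scheme.R
<tilt_scheme> +/-60 deg, 1 deg increment, groups of 4, 121 images
  total dose 110 e-/A^2 (0.9091 per image)
first 9 angles: 0, 1, 2, 3, -1, -2, -3, -4, 4
```

```
$ Rscript analysis/06_morphometry.R
curved/ridge: thickness 8.18 nm (peak 0.69, dip 0.02)
curved/flat: thickness 5.43 nm (peak 0.56, dip 0.01)
curved eisosome: relative membrane thickness 1.51
shallow eisosome: relative membrane thickness 0.95
cohort 1: shallow 1.03 +/- 0.08, curved 1.54 +/- 0.09, p = 0.002188
coat circle fit: diameter 45.1 nm (truth 45.0 nm), rms 0.08 px
```

The coated, curved phantom measures ~1.5× thicker than its nearby
plasma-membrane patch while the uncoated shallow one stays at ~1; seeded
3-vs-3 cohorts separate the two categories at p < 0.01, and the circle fit
recovers the built-in 45 nm coat diameter to 0.2%.

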