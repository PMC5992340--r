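---
title: "Correlative registration and membrane-coat morphometry: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlative registration and membrane-coat morphometry: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`eisoclem` re-creates, as a tested pipeline over synthetic phantoms, the
analysis chain used to show that BAR-protein coats sit on curved — but not
on shallow — eisosome membranes in correlative cryo-fluorescence /
cryo-electron tomography data: fiducial-based FM-to-EM registration,
focal-plane attachment screening, grouped dose-symmetric tilt planning,
spline-guided sub-volume extraction with 2D collapse, regularized-likelihood
2D averaging, and thickness/curvature morphometry. This vignette documents
the models, the tunable parameters, and the design decisions; the README
shows the worked example.

# The registration model

Fiducial beads visible in both modalities give paired coordinates
$(f_i, e_i)$. The fitted map is the least-squares minimizer of
$\sum_i \lVert e_i - (A f_i + t) \rVert^2$. The default model is a full 2-D
affine ($A$ unconstrained): it absorbs magnification anisotropy and shear
between the optical and electron images, which a similarity transform
cannot. A similarity model ($A = sR$, $R$ orthogonal, reflection permitted,
solved by the Procrustes/Umeyama closed form) is available by flag; on data
that are truly similarity-distorted the two agree to numerical precision,
which is tested.

Prediction accuracy is estimated by leave-one-out: each bead in turn is
excluded, the map refitted, and the excluded bead's prediction miss
recorded; the mean miss estimates the error at the target. This estimator
was chosen because it requires no noise model and is directly validated in
the tests against genuinely held-out beads (agreement within a factor of
two on average).

Coordinates are 0-based, pixel-centre origin, (x, y) ordered, everywhere —
a single convention shared by every file the package reads or writes, which
avoids the classic half-pixel registration bug.

Spot positions are refined by least-squares fits of an isotropic 2-D
Gaussian plus constant background inside a user-sized window. Degenerate
windows are flagged per spot rather than aborting a batch. Focus heights
come from a per-plane focus metric (window peak intensity by default,
gradient-energy sharpness as a cross-check) with parabolic sub-plane
interpolation. Attachment screening compares each signal's focus height
with a reference (carbon film or fiducials); the default threshold is 1
micrometre, inclusive — an order of magnitude below the ~3.6 um offset of a
clearly detached section, and comfortably above focus-estimation noise at a
0.3 um plane spacing.

# Tilt-scheme generation

The grouped dose-symmetric ordering alternates sides of the untilted view
in blocks (default four images, 1 degree increment, +/-60 degrees),
each block continuing outward on its side. Two conventions are pinned down
explicitly because the prose description leaves them open: the 0-degree
image counts as the first image of the first group (so the first block is
{0, 1, 2, 3} for groups of four, and for groups of one the classic
0, +1, -1, +2, -2 ordering results), and the first group tilts positive by
default (configurable; the downstream analysis is insensitive to the
choice). Dose is split uniformly, 110 e-/A^2 total by default, because only
the series total and a constant dose rate are specified for the acquisition
this emulates.

# The membrane phantom

The phantom is an extrusion along x of a 2-D cross-section in the (y, z)
plane, which makes every geometric truth analytic: a flat
plasma-membrane sheet (normal +y, extracellular side at larger y)
interrupted by a furrow-like invagination with tip radius $r$ and depth
$d$ (a circular arc, plus straight walls when $d > 2r$). Membrane density
is a Gaussian shell of sigma 2 nm around the midline, so the true
thickness under the half-maximum width rule is $2\sqrt{2\ln 2}\,\sigma
\approx 4.7$ nm, a realistic bilayer-scale figure at the 7 A working pixel
size. The optional coat is a second shell at `coat_offset` on the
cytoplasmic side of the curved ridge (central 75% of the arc), so the coat
diameter is exactly $2(r + \mathrm{offset})$.

Orientation matters under a missing wedge: the sheet normal is placed
in-plane (perpendicular to the beam axis z), mirroring the favourable
sections selected in practice, so the flat membrane survives wedge
filtering while furrow walls (normals along the beam) fade — the same
anisotropy real tomograms show. The wedge filter zeroes Fourier
coefficients whose (ky, kz) direction lies more than `max_tilt` (default
60 degrees) from the in-plane axis, with the tilt axis fixed to the
extrusion axis; the mask is symmetric under frequency negation so the
output stays real. Noise is additive white Gaussian applied before wedge
filtering — the simplest model that lets the classification SNR be dialled;
it does not attempt CTF, dose-dependent damage, or section-compression
artifacts, so passing tests demonstrate correctness of the pipeline's
logic, not robustness to every real-data pathology.

Default geometry: furrow radius 18 nm, depth 30 nm, coat offset 4 nm
(coat diameter 44 nm, inside the 32-58 nm regime reported for BAR-protein
lattices), noise SD 0.5 relative to a membrane peak of 1. The contrast
level of the source tomograms is not published, so the default SNR was
chosen once as the level where single-eisosome class averages look
comparable to published ones (membrane clearly visible in the average, not
in single cross-sections) and kept fixed. With a 4 nm offset the membrane
and coat peaks merge into one broadened band, reproducing the
"major single or double peak" morphology and a curved-to-shallow relative
thickness near 1.6; a larger offset (6.5 nm) renders the coat as a
discernible second layer and is used where the analysis needs one (circle
fits, class-quality comparisons), matching the fact that coat curvature was
only ever measured where a coat was visible.

Shallow phantoms are uncoated indentations (depth ~4-7 nm, radius
~25-32 nm); curved phantoms are coated furrows (depth ~27-33 nm, radius
16-20 nm). The generator couples coat presence to the curved category, as
observed, but both are independently settable for negative controls.

# Extraction and collapse

Clicked membrane points (15 nm nominal interval) are interpolated by
natural cubic splines parameterized by chord length; smoothing defaults to
zero because clicks at 15 nm spacing are already sparse relative to the
membrane's curvature scale. Arc length uses dense polyline quadrature
(relative error < 1e-4). Boxes are cubic, axis-aligned, trilinearly
interpolated, centred at arc positions $B/2 + k(1-o)B$ (40% overlap by
default); out-of-bounds voxels are zero-padded and boxes with more than 25%
padding are excluded from averaging.

Collapse projects each box along the local spline tangent, averaging over
the central 60% of the depth. The box depth of the original procedure is
unstated; restricting the projection limits contributions from membrane
curving out of the cross-section plane, and the restriction is recorded in
provenance. The projection is a mean, not a sum, so collapse commutes with
binning up to interpolation error. The image frame puts the in-plane "up"
reference along the projection of the tomogram z axis (falling back to y
when the tangent is near z); the in-plane angle prior is the rotation
carrying the image y axis onto the extracellular membrane normal, whose
side is fixed by the click-ordering convention. Applying the prior rotates
every cross-section so the membrane runs horizontally with the
extracellular side up — the convention all morphometry assumes.

# Regularized-likelihood 2D averaging

Images are modelled as a transformed class average plus white Gaussian
noise; transforms run over a discrete grid of in-plane rotations
(prior +/- 15 degrees by default, 2 degree step — a local search standing
in for the production classifier's, whose parameters are unpublished) and
shifts (+/- 3 px). The E-step marginalizes responsibilities over classes
and transforms; the M-step recomputes class averages as
responsibility-weighted aligned means shrunk toward zero by a ridge weight
(default 1, acting like one phantom zero-image per class), then the class
fractions, then the noise sigma in closed form. Updating sigma from the
current averages before updating the averages keeps every step a
generalized-EM ascent, so the penalized marginal likelihood is
non-decreasing — asserted with tolerance 1e-6 in every test run. Total
rotation angles are snapped internally to the angle-step grid so
resampling maps can be cached and shared; reported rotations keep exact
prior-plus-offset values, which is why a zero-width search returns the
priors verbatim.

Initialization averages a seeded random partition of the input and adds a
small noise floor so classes never start identical; everything downstream
is deterministic given the seed. K, iteration count (default 25;
scaled-down runs use 8-15) and the ridge weight are engineering choices,
since the production run's values are unreported; multiple K are run
side by side (`run_multi`), mirroring the practice of classifying each
membrane several times to handle curvature heterogeneity.

Class selection is deliberately not automated: `select_classes` records an
explicit user choice, displaying a quality score alongside — the
high-frequency energy of the average inside a central band mask,
normalized by squared band peak and band area. The score rises with sharp,
layered averages (a discernible coat raises it) and falls with blur, making
it a reproducible aid for, never a replacement of, visual selection. For
a K = 1 average the absolute orientation of the aligned frame is a gauge
freedom; tests compare averages and recovered shifts modulo that gauge.

# Morphometry

Band profiles average the central 7 pixel columns of a class average,
giving one density profile across the membrane. The thickness rule: the
threshold is the mean of the highest peak and the deepest local minimum on
the extracellular side of that peak; the width is the contiguous
at-or-above-threshold interval containing the peak, with endpoints
interpolated linearly between samples (at 7 A pixels the measurement is
quantization-limited otherwise; a whole-sample mode is provided). "Major
peak" is formalized as that contiguous interval so merged membrane+coat
double peaks measure as one thickened band, deterministically. A profile
whose extracellular side offers no local minimum, or whose peak sits at the
profile end, is flagged as failed rather than measured; plateaued maxima
use the plateau centre and carry a flag. The rule is exactly invariant to
intensity scale and offset, and a boundary sample below its neighbour
counts as a dip so that clean Gaussian bands on a zero baseline measure
their FWHM.

Relative membrane thickness divides each eisosome's thickness by that of
its paired plasma-membrane patch. The pairing distance in the phantoms is
40-55 nm rather than the ~200 nm of real tomograms, because a desk-scale
volume (about 34 x 78 x 111 nm) cannot hold both at full separation; the
patch is still well clear of the furrow and coat. When several patches are
available the nearest is used and logged. Cohorts are compared with a
two-tailed Welch test (unpooled variances, Satterthwaite degrees of
freedom), implemented in closed form and verified against the reference
implementation to 1e-9.

Coat curvature is a least-squares circle through points along the densest
coat arc: an algebraic (Kasa) seed refined by geometric Gauss-Newton — the
referenced utility's internals are unpublished, so the contract is simply
"least-squares circle", and three exact points reproduce their circle to
machine precision. The automated stand-in for clicking picks, along rays
from the furrow centre, the outermost radial local maximum (the outer
density layer an annotator would click), with parabolic sub-pixel
refinement; rays where no separate layer exists are dropped.

# Problem sizes and what the tests show

Phantom volumes default to 48 x 112 x 160 voxels at 7 A (the working,
binned pixel size of the emulated reconstructions); classification-scale
checks use 200 images of 64 px, and end-to-end cohorts use 3 shallow + 3
curved phantoms per repetition with 32 px boxes, 20 seeded repetitions —
sizes chosen so the whole suite runs on a laptop while every stage still
operates in its intended regime. Passing tests demonstrate that the
pipeline recovers known ground truth under the stated noise, wedge and
geometry model; they cannot certify behaviour under real-data effects the
generator does not emulate (CTF, gold fiducials, knife marks, crevasses,
non-Gaussian noise).

# Known limitations

- 2-D registration only; no chromatic-shift or z-aware correction.
- The classifier is CTF-blind and offers no resolution estimation; it is a
  phantom-scale reimplementation of the analysis logic, not a drop-in for a
  production package.
- Thickness is a projected, band-averaged quantity; strongly tilted
  membranes dilute it, which is why padded or misaligned boxes are excluded
  rather than corrected.
- The missing-wedge model zeroes coefficients sharply; no CTF or dose
  weighting.
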