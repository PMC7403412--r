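---
title: "Simulated quantitative phase imaging of sperm cells: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated quantitative phase imaging of sperm cells: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spermqpi)
```

## Scope

`spermqpi` is a desk-scale, fully synthetic re-creation of a quantitative
phase imaging (QPI) workflow for classifying human sperm cells under stress
conditions (cryopreservation, hydrogen peroxide, ethanol). No clinical
images are distributed with this package; instead a phantom generator
stands in for the microscope and its subjects, and every downstream stage —
off-axis interferogram formation, Fourier-transform demodulation, Goldstein
branch-cut unwrapping, retention quality control, and two classification
paths — operates on simulated data exactly as it would on real camera
frames. The point of the package is that the entire measurement chain is
executable and checkable: every stage can be fed inputs with known ground
truth.

## The phantom

A cell is modeled as three compartments, each a thickness map $t(x,y)$ in
micrometres:

* **Head**: an ellipse (default $4.5 \times 3.0\ \mu m$, WHO-typical) whose
  thickness has a flat plateau (default $2.5\ \mu m$) with a smooth cosine
  taper over the outer 15% of the normalized radius. The plateau-plus-taper
  profile was chosen over a plain cosine dome so that thresholding at half
  the peak phase — the operational definition used by the head segmenter —
  recovers close to the true ellipse area.
* **Midpiece**: a $4.0 \times 0.6\ \mu m$ capsule with elliptic
  cross-section, thickness $0.6\ \mu m$.
* **Tail**: a $40\ \mu m$ centerline with a gentle quadratic bend and a
  sinusoidal lateral wave, stamped with constant thickness $0.1\ \mu m$
  (the ~100 nm scale that makes sperm tails hard to image) and width
  $0.45\ \mu m$, clipped at the field edge.

Cells sit on a reflecting substrate, so the optical path is traversed
twice and phase is

$$\phi(x,y) = \frac{4\pi}{\lambda}\,\Delta n\; t(x,y),$$

with $\lambda = 0.6328\ \mu m$ (He–Ne line) and index contrast
$\Delta n = 0.05$ by default. A transmission-geometry user should halve
this. The defaults give a head plateau phase of
$4\pi \cdot 0.05 \cdot 2.5 / 0.6328 \approx 2.48$ rad and a tail phase of
$\approx 0.099$ rad. The sampling is $0.108\ \mu m$/pixel (a 6.5 $\mu m$
camera pixel behind a 60× objective) on a 512×512 field.

Real instruments do not resolve a discontinuous silhouette edge; an
optional `band_limit` parameter apodizes the phase spectrum with a smooth
order-8 super-Gaussian window, emulating finite optical resolution. It is
off by default because it slightly spreads support outside the silhouette;
the round-trip analyses below switch it on.

### Condition classes

The four classes are parametric proxies for the qualitative membrane and
tail mechanisms attributed to each stressor, scaled by an
`effect_size` $\in [0,1]$:

| class | perturbation at `effect_size = 1` | dose statistic |
|---|---|---|
| normal | none (identity) | — |
| cryo | head peak phase −30%; boundary roughness | mean head phase (reduction) |
| h2o2 | tail waviness ×3; head phase-texture variance | tail curvature energy |
| ethanol | head axis skew ±15% (eccentricity up ~15–20%); boundary roughness | head eccentricity |

These perturbations exist to make classification learnable and tunable;
they make no claim of biophysical fidelity. `effect_size = 0` reproduces
the normal class bit-for-bit, which gives a clean null control: every
class-separating statistic and both classifiers must collapse to chance
there. The boundary roughness is a random low-order Fourier series on the
boundary angle (harmonics 3–8), and the head texture a correlated Gaussian
field; both are seeded, so any phantom is reproducible from
`(params, seed)`.

Datasets draw per-cell pose jitter — rotation uniform on $[0, 2\pi)$,
translation keeping the head in-field, isotropic size jitter ±10% — so
that classifiers cannot key on position or orientation.

## Interferogram formation

Off-axis holography encodes phase in intensity fringes:

$$I(x,y) = a(x,y) + b_0 \cos\!\big[2\pi(f_x x + f_y y) + \phi(x,y) +
\eta(x,y)\big],$$

followed by optional Poisson shot noise and quantization to the camera bit
depth (default 16). The default carrier is $(f_x, f_y) = (0.125, 0.125)$
cycles/pixel — diagonal fringes with well-separated sidebands; the source
instrument's fringe density is not documented, so this is a package
default. The background $a(x,y)$ can carry a smooth polynomial
non-uniformity to exercise background subtraction downstream.

Two noise regimes bracket the source-coherence trade-off at the heart of
the instrument design:

* **psc** (partially spatially coherent): $\eta$ is a correlated Gaussian
  field (white noise blurred with a 10-pixel Gaussian) scaled to a target
  std of 0.020 rad — the ±20 mrad empty-field spatial phase sensitivity
  characteristic of this instrument class.
* **coherent** (direct laser): the same correlated field plus broadband
  speckle-like phase noise (std 0.15 rad) and one weak parasitic fringe
  inside the demodulation passband. Only a fraction of the broadband term
  survives sideband filtering, but the parasitic fringe does not average
  away, so the reconstructed empty-field noise is strictly worse than psc
  (about 2×), reproducing the qualitative laser-vs-PSC gap without
  modeling physical coherence.

`calibrate_phase_noise()` closes the loop: it synthesizes empty fields,
runs the full reconstruction, removes piston/tilt, and reports the mean
spatial std. With psc defaults this lands within a few percent of the
20 mrad set-point, because the correlated noise (correlation length 10 px,
bandwidth ≈ 0.016 cycles/pixel) passes the sideband filter essentially
unattenuated.

## Phase reconstruction

`demodulate()` implements the standard single-shot Fourier-transform
method: FFT, select one sideband, shift its center bin to DC, inverse
transform to the complex signal $c(x,y)$, and read
$\phi = \operatorname{atan2}(\mathrm{Im}\,c, \mathrm{Re}\,c)$. Values lie
in the half-open interval $(-\pi, \pi]$: the four-quadrant arctangent's
$-\pi$ edge is mapped to $+\pi$.

Numerical choices that matter:

* **Sideband filter**: default radius $0.45\,|f|$ with a `gaussian_soft`
  profile — flat to 60% of the radius, then a Gaussian rolloff
  ($\sigma = 0.15$ radius). A hard disk rings visibly at the tail's
  ~0.1 rad amplitude; the flat-top soft-edge profile keeps the passband
  exact while suppressing ringing. The filter never includes the DC bin,
  errors out if its support reaches DC, and records a provenance warning
  when the radius exceeds half the carrier distance.
* **Borders**: a 16-pixel border is excluded from all quantitative
  comparisons (FFT periodicity artifacts live there).
* **Coordinates**: row-major, origin top-left, $x$ = column index,
  frequencies in cycles/pixel. Carrier estimates are reported in the
  half-plane $f_y \ge 0$ so the two conjugate sidebands of a real image
  map to one representative.
* **Background subtraction**: default is a polynomial fit (order 2) to
  the cell-free pixels, subtracted everywhere. The cell mask, if not
  supplied, is derived by flattening with a first-order plane fit and
  thresholding the residual at $\max(0.05, 4\,\mathrm{MAD})$ — this keeps
  the faint tail out of the background sample, which matters at the
  sub-2-mrad level. A `reference_frame` mode subtracts an empty-field
  reconstruction pixel-wise when one is available.

### Round-trip fidelity

The pipeline's headline numerical property is that a noise-free round trip
(band-limited phantom → interferogram → demodulation → unwrapping →
background subtraction) recovers the truth to better than 1 mrad RMS over
the interior, tail included. Achieving that requires the demodulation
passband to cover the bandwidth of $e^{i\phi}$ — which is wider than the
bandwidth of $\phi$ because the head swings through ~2.5 rad. The
round-trip analyses therefore use a carrier of $(0.25, 0.25)$
cycles/pixel with filter radius 0.24 and a phantom `band_limit` of 0.08
cycles/pixel; with those settings the measured error is ≈ 0.4 mrad RMS.
At the default carrier the same round trip sits at a few mrad — still far
below the 20 mrad noise floor of the simulated instrument, but the
acceptance analyses use the wide-carrier configuration.

## Goldstein unwrapping

The wrapped phase is unwrapped with the classic residue/branch-cut
algorithm, decomposed into three independently testable operations:

1. `compute_residues()`: the wrapped loop integral around every 2×2 pixel
   loop, quantized to charges in $\{-1, 0, +1\}$. A brute-force
   loop-integral oracle (implemented independently in the test suite with
   a different principal-value formula) must agree exactly.
2. `place_branch_cuts()`: nearest-neighbour growing-radius pairing of
   opposite charges, grounding a residue to the border when the border is
   strictly nearer (or no partner exists within the search radius).
   Residues are visited row-major and equal distances break by row-major
   candidate order, making cut placement bit-reproducible. Cuts are
   rasterized with 4-connected Bresenham lines.
3. `integrate_phase()`: breadth-first flood fill from a seed (the pixel of
   maximum fringe modulation $|c|$, when known), adding the wrapped
   neighbour difference at each step. Cut pixels are barriers, filled last
   by nearest-neighbour extension — still congruent to the input mod
   $2\pi$ — and flagged in a low-confidence mask rather than silently
   trusted.

On residue-free inputs the result equals Itoh row/column line integration
up to a global $2\pi k$ piston, and is independent of the seed pixel; both
properties are enforced in the tests. On hopeless inputs (uniform noise)
the report's residue count and low-confidence fraction document the
failure instead of hiding it, and the QC stage uses exactly those numbers.

## Quality control

The retention screen mirrors a three-criterion manual protocol — correct
unwrapping, flat background, exactly one cell in the field — with declared
operational thresholds, since the source protocol names the criteria but
not the numbers:

* unwrap: residue density ≤ 1 per kilopixel and ≤ 0.1% of neighbour jumps
  above $\pi$;
* background: RMS outside the cell mask ≤ 0.05 rad;
* single cell: Otsu threshold on the positive-phase histogram (fallback
  0.1 rad), morphological closing with a 3-px disc so the faint tail joins
  the head rather than fragmenting, removal of components < 50 px,
  8-connected labelling, then exactly one component with a white-pixel
  count in [500, 30% of the field].

Every threshold is monotone: tightening it never retains an image that the
looser setting rejected, a property the tests exercise directly.

## Classification

Both classification paths consume QC-passing phase maps and use the same
stratified 70/30 split (per-class test count = `round(0.3 n)`, remainder
to train — reproducing 720 test images from a 2,400-image class, 2,880
from four). Confusion matrices fix **rows = ground truth**, columns =
prediction, class order (normal, ethanol, h2o2, cryo); per-class
sensitivity, specificity and accuracy are one-vs-rest, macro averages are
unweighted, and the overall accuracy (trace/total) is reported alongside.

**Feature path.** Eleven features from the segmented head: area,
perimeter, major/minor axis, eccentricity, circularity (all physical units
via the pixel pitch), mean/max phase, phase variance, skewness, and
histogram entropy. The exact feature list of the source protocol is not in
its main text, so this composition — head morphology plus phase texture —
is frozen here as the package's definition. Classifiers are an RBF SVM,
Gaussian naive Bayes, and kNN (k = 5); features are z-scored with training
statistics. kNN distance ties are resolved by the seeded RNG of the
underlying implementation rather than by sample index, which keeps runs
reproducible at fixed seed.

**CNN path.** No deep-learning framework is assumed: the package ships a
small 4-block convolutional network (3×3 convolutions with channels
8-16-32-64, ReLU, 2×2 max-pooling, a 64-unit dense layer, softmax; about
10^5 parameters) with exact analytic gradients implemented in C++ and
verified against numerical differentiation. Training follows the fixed
protocol of the study it emulates: stochastic gradient descent with
momentum, initial learning rate $10^{-4}$, 30 epochs; momentum 0.9, batch
size 8, and an exponential learning-rate decay of ×0.91 per epoch are
package defaults. The decay matters when training from random
initialization: constant-lr SGDM either under-trains (large batches) or
oscillates around the minimum late in training (small batches); with the
decay the per-epoch training loss descends near-monotonically while test
accuracy stays above 0.9 at 200 images/class. Inputs are fixed-size windows (128
source pixels) centered on the high-phase centroid — i.e. the head, with
midpiece and proximal tail in frame — resampled to 64×64, in radians, and
standardized by training-set statistics. The fixed physical window was
chosen over a cell-bounding-box crop because the box size varies wildly
with tail orientation, destroying scale consistency; and 64×64 input
(rather than 128×128) keeps a 30-epoch run at 200 images/class to a few
minutes on one CPU core without visible accuracy loss at these problem
sizes. Training is deterministic given the seed.

## What the tests do and do not show

The synthetic generator produces exactly one fixed-anatomy cell per image
with parametric, class-consistent perturbations and stationary background
noise. Real sperm QPI data has debris, touching cells, focus drift,
refractive-index variation, motile blur, and biological variance that no
part of this generator emulates. Passing the acceptance suite therefore
demonstrates that the *pipeline* is correct and well-calibrated — the
reconstruction chain is faithful to sub-mrad level, the noise regimes hit
their sensitivity targets, the classifiers can recover class structure
that is present and find nothing when it is absent — not that any
particular clinical accuracy would be achieved. The headline clinical
accuracies of the study this package emulates depend on non-deposited
patient images and pretrained networks, and are deliberately out of scope.

## Problem sizes

The shipped analyses use a 512×512 field for round-trip fidelity, 256×256
fields and 200 images/class for classification, 20 empty-field trials for
sensitivity calibration, and 100 random 64×64 fields for the residue
oracle — sizes chosen so the whole suite runs in minutes on a single CPU
core while keeping every statistical check comfortably powered.
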