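---
title: "Simulating and reconstructing CCEIT brain-stroke images: models, assumptions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and reconstructing CCEIT brain-stroke images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cceit)
```

## Overview

Capacitively coupled electrical impedance tomography (CCEIT) measures the
complex capacitance between pairs of electrodes that are insulated from the
skin, avoiding the electrode-contact impedance problems of galvanic EIT.
Because no clinical CCEIT datasets exist, studies of learned reconstruction
must generate their training data by simulation. This package implements
that whole loop: a parametric head phantom with stroke lesions, a forward
solver for the insulated 16-electrode belt, linearized reconstruction
baselines, an adversarially trained neural reconstructor, and the metrics
used to judge image quality. This vignette records the models, the
parameters that matter, and the numerical decisions, so that results can be
interpreted and the package modified with open eyes.

## The head phantom

The phantom is a 2D axial cross-section built from tilted ellipses,
deliberately in the spirit of the Shepp-Logan phantom. Four electrically
distinct regions are modelled: skin+skull (one dielectric value), two brain
hemispheres, and cerebrospinal fluid (CSF). The head outline is fixed at
semiaxes 77 x 105 mm, which gives the 575 mm circumference of an average
adult head (`ellipse_perimeter(77, 105)`); the belt geometry is therefore
constant across phantoms. Each hemisphere is the intersection of an "Inner"
ellipse (the brain boundary) with the union of an upper and a lower lobe
ellipse, clipped to its side of a tilted midline; CSF is the remaining
interior of Inner plus five explicit CSF ellipses (a central one and four
satellites placed on its outward normals) which override brain tissue. The
interior of Inner not covered by a hemisphere is assigned to CSF because
the four regions must partition the head and the inter-hemispheric space is
CSF anatomically.

Geometry parameters are sampled from the constraint tables shipped at
`system.file("extdata", "head_constraints.yaml", package = "cceit")`. Every
entry is a `mean ± half-range` window; the sampler draws within the window
(truncated normal with `sd = half-range / 2` by default, uniform as an
option) and enforces, by rejection:

* per-element circumference and axes-ratio windows where these are
  consistent with the size windows (Inner, the central CSF ellipse, the
  four satellites);
* skull containment of the Inner ellipse;
* the published whole-image area constraints: brain area 23.0 ± 6.0 % of
  the image, skin+skull ("rest of head") 13.5 ± 5.5 % of the image, CSF
  23.0 ± 6.0 %, and a left/right hemisphere area ratio of 98.5 ± 7.5 %.

Two interpretation points deserve emphasis, because the printed tables are
not mutually consistent under every reading:

* **Size entries.** Negative size entries are per-semiaxis offsets against
  the reference ellipse; positive entries are absolute semiaxes. This
  reading is fixed by the circumference table: it gives Inner semiaxes
  (63, 91) mm with perimeter 487.8 mm against the printed 487.5 ± 53.5,
  and satellite perimeters inside their printed windows, whereas a
  full-axis reading misses those windows entirely.
* **The CSF area base.** With the head outline fixed and Inner inside it,
  brain + CSF areas sum to the Inner interior, about 33 % of an image
  whose skin+skull share is 13.5 %. Brain and CSF cannot therefore both be
  23 % *of the image*. Measured against the *head* area, the mean geometry
  gives a CSF share of 22.4 %, consistent with the printed 23.0 ± 6.0. The
  package defines the CSF fraction relative to head area and the brain and
  rest-of-head fractions relative to image area; all three then match
  their printed means simultaneously.

The hemisphere-lobe rows of the circumference/axes-ratio table are
infeasible jointly with the lobe size windows (for the left-lower lobe no
size inside its windows satisfies both its circumference ratio and its
axes ratio). They are computed as diagnostics but not used for rejection;
enforcing them either exhausts the sampler or drives it into a biased
corner of small-Inner geometries that corrupts the area statistics.

The image field of view is 234 mm. This value is derived, not tuned: it is
the extent at which the fixed skin+skull annulus (head outline minus the
mean Inner ellipse) occupies exactly its printed mean share, 13.5 % of the
image; at the same extent the mean brain share is 22.5 % against the
printed 23.0. A 64 x 64 image over 234 mm gives 3.66 mm pixels.

The second generation approach perturbs all raw parameters of a frozen
base model with Gaussian noise of standard deviation `relative_sd` times
each parameter's half-range (one knob, natural units per parameter;
default 0.05) and re-validates. The bases are 50 accepted draws from the
constraint sampler frozen by seed, standing in for manually fitted models.

```{r phantom, eval = FALSE}
tab <- load_constraint_tables()
g <- sample_geometry(tab, seed = 1)
unlist(area_fractions(g))
ph <- build_healthy_phantom(g, assign_region_properties(seed = 1))
```

## Dielectric properties and stroke lesions

Region dielectric values are Gaussian draws from published 64 MHz region
statistics (`region_priors()`: skull+skin 102 ± 29 mS/m, brain 378 ± 59,
CSF 788 ± 207, with matching permittivities), redrawn until the
physiological ordering CSF > brain > skull+skin holds for both properties.
The per-tissue table behind those statistics (`tissue_table()`) is carried
for reference; the phantom itself is piecewise constant per region, and 64
MHz is used throughout so the values are comparable with 1.5 T electrical
properties tomography.

Strokes are circular lesions placed on one of six rays that approximate
the main cerebral arteries, fanning from the midpoint of the upper half of
the Inner ellipse's vertical axis at 12, 80, 135, -12, -80 and -135
degrees from vertical. Hemorrhagic lesions centre at a random artery point
inside the brain and take blood values (1230 mS/m, relative permittivity
76); ischemic lesions centre on the artery just outside the brain (so the
lesion is the circle-hemisphere intersection) and scale the host
hemisphere conductivity by a uniform factor in [0.60, 0.70] — the "65 ±
5 %" specification read as a range — with permittivity unchanged. The
radius is uniform between 15 mm and the distance, along the chosen ray,
from the last CSF crossing to the brain edge; if that gap is under 15 mm
another artery is tried. The CSF region is subtracted from every lesion
and the result clipped to its hemisphere. The near-vertical ±12° rays
occasionally run entirely up the inter-hemispheric fissure (CSF) in a
sampled geometry; the artery-retry loop makes lesion insertion robust to
this.

## Forward model

The solver works in single-frequency phasor form at 64 MHz: tissues enter
as the complex relative permittivity `eps' - j sigma / (omega eps0)`
(`complex_permittivity()`). Although the physical device uses pulse
excitation, the tissue properties are specified at 64 MHz, so a
single-frequency analysis is the consistent abstraction. The quasi-static
potential solves `div(eps grad V) = 0` with the excited electrode at 1 V
and all other electrodes and a grounded screen at 0 V. Capacitances are
Gauss-law surface integrals of the displacement flux over a contour one
cell off the measuring electrode, divided by the potential difference;
they are per-unit-depth (F/m, 2D), which is immaterial after per-channel
standardization. A full frame excites each electrode in turn and reads all
others: N(N-1) ordered pairs, 240 at 16 electrodes, 992 at 32.

The sensor model (`sensor_model()`) wraps a dielectric insulation layer
around the head outline (the coupling capacitance of CCEIT), with metal
electrode arcs on its outer surface — 16 sectors of 22.5° with 80 % metal
coverage — and a grounded screen 20 mm further out. The insulation is 4 mm
of relative permittivity 4 by default. Both are configurable; the
thickness default is chosen so the layer spans at least one cell on every
supported solver grid (64² and up), keeping the coupling capacitance
represented at the coarse training resolution.

Discretization is a regular Cartesian finite-volume grid (5-point stencil,
harmonic-mean face permittivities), factorized once per phantom and reused
for all 16 excitations, with an equivalent-real block formulation of the
complex system. Two measures control boundary staircase error: material
permittivities are area-weighted by 3 x 3 sub-pixel sampling at tissue and
insulation boundaries, and faces adjacent to metal use ghost-cell
conductances based on the true sub-pixel distance to the electrode
surface. With these, the discretization reproduces the concentric-annulus
closed form (`annulus_capacitance()`, a cylindrical capacitor) within 2 %
at 256², and capacitance frames of a smooth phantom agree between 128² and
256² grids to a median of about 2.6 % (mean about 4 %) over the 240 pairs.
The residual is first-order boundary error, dominated by the angular
quantization of the electrode arc ends; pairs with the smallest
capacitances show the largest relative differences. The default training
grid is 64², the coarsest the solver accepts: dataset generation needs
only a self-consistent simulator, not grid-converged absolute values.

Measurement noise is peak-referenced: i.i.d. Gaussian noise of standard
deviation `max |C| / 10^(SNR/20)` added to the real and imaginary parts,
the convention behind "30 dB peak SNR".

## Linearized baselines

The sensitivity (Jacobian) matrix maps per-pixel complex permittivity
changes to capacitance changes at a reference field (homogeneous
brain-mean tissue in the head outline, the difference-imaging convention).
It is assembled from the 16 single-electrode solutions through the adjoint
identity of the symmetric discrete system — the derivative for pair (i, j)
is a conductance-derivative-weighted dot product of the two solutions'
face potential differences — and verified against finite differences
(first-order residual decay; 1 % agreement at small perturbations for
interior pixels). Conductivity images are reconstructed from the imaginary
part of the capacitance change, since conductivity enters the complex
permittivity imaginarily: linear back projection applies the transposed,
per-pixel-normalized operator; the truncated pseudoinverse solves by SVD
with the rank chosen at the Picard elbow unless overridden. On this
operator, useful localization needs ranks around 100-150 of the 240; the
automatic elbow errs conservative, so the truncation override matters in
practice.

## Adversarial reconstructor

The reconstructor maps the flattened 2 x 240 standardized measurement
frame (480 values) to a 64 x 64 conductivity image in [0, 1]. It is built
from exactly the primitives defined above — linear layers, batch
normalization, leaky ReLU (slope 0.2), sigmoid output — as a dense
network: 480 → 512 → 512 → 4096 for the generator, with batch
normalization on the hidden layers, and a discriminator that concatenates
the image with its conditioning measurement vector and maps 4576 → 128 →
32 → 1 through a sigmoid. Dense layers, rather than the conv/deconv U-Net
blocks common in this literature, are a deliberate design for this
implementation: the mapping's input is an unstructured measurement vector,
R's efficient numerical primitive is the BLAS matrix product, and the
defining structural property — only the entry layer's weight count depends
on the measurement-vector length — holds for the dense architecture
exactly as for the convolutional one (and is asserted by a weight-shape
audit test). Widths are configurable.

Training follows the Pix2Pix recipe: the discriminator minimizes binary
cross-entropy with labels 1 for ground truth and 0 for reconstructions;
the generator minimizes the adversarial term plus `lambda = 100` times the
L1 reconstruction error; Adam with `beta1 = 0.5`; starting learning rates
1e-3 (generator) and 1e-8 (discriminator), constant by default. The
extreme learning-rate asymmetry is the point, not an accident: with a
16-electrode input the discriminator otherwise overpowers the generator
and its loss collapses to zero, so it is kept near-static while the
L1-dominated generator learns; the training log tracks the discriminator
loss and warns if it collapses below 1e-4 for three consecutive epochs.
The per-epoch quality index is the mean relative error
`||yhat - y|| / ||y||` (L2 norms) on the test split. All backpropagation
is hand-derived and verified against numerical differentiation in the test
suite. Training is seeded and reproducible bit-for-bit on a fixed BLAS
configuration.

## Datasets and evaluation

`build_dataset()` draws condition labels uniformly over healthy,
hemorrhagic and ischemic (the published class counts of 66,758 / 66,468 /
66,774 in 200,000 are consistent with uniform thirds), generates phantoms
with both approaches, simulates clean frames, splits 75:25 into train and
test, adds peak-SNR noise (default 30 dB) once per sample, and z-scores
each of the 480 input channels with statistics from the training split
only — raw capacitances span orders of magnitude across pairs, so literal
raw inputs would be poorly conditioned; the standardization constants are
recorded in the container. Clean frames are retained so evaluation can
re-noise them at other SNR levels, and training can optionally re-draw the
augmentation noise each epoch. Targets are conductivity maps min-max
normalized to [0, 1] over the head support with background 0. Every sample
carries its seed record and regenerates bit-exactly from it; samples are
generated from independent child streams of one root seed, so the dataset
is order-independent and individually reproducible.

Image quality is summarized by RMSE, PSNR, global SSIM, and the 2D
(Pearson) correlation, with means and dispersions per SNR level and
histogram exports. Two metric details are intentional: PSNR uses the form
`10 log10(N max(yhat) / sum((y - yhat)^2))` as printed in the source
tables — it references the reconstruction peak linearly, unlike the
conventional squared-peak form, which is available behind a flag — and
SSIM is the single global formula with `c1 = (0.01 L)^2`,
`c2 = (0.03 L)^2`, `L = 1`, not the sliding-window variant. Comparisons
with windowed-SSIM numbers from other work should account for this.

## Problem sizes and what the tests show

The package's default scales are desk scales: 2,000 + 2,000 training
samples on the 64² solver grid and a 512-wide generator, which train in
minutes on one CPU; the full-scale study (100,000 + 100,000 samples,
100 epochs) is reached by raising the configuration numbers, and its
reported quality (SSIM ≈ 0.81 at 60 and 30 dB) is not expected from the
desk scale — though in practice a 4,000-sample, 20-epoch CPU run already
reaches test-set SSIM near 0.8 at 60 dB and clearly beats linear back
projection (SSIM ≈ 0.2). The test suite checks the qualitative claims at
desk scale: decreasing test error, adversarial stability under the
(1e-3, 1e-8) learning-rate pair, superiority over LBP, and monotone
degradation with noise.

Passing these tests shows that the pipeline is internally consistent and
that the generator learns the simulated inverse map. It does not show
clinical validity: the phantom is 2D and piecewise constant, electrode
geometry is idealized, the solver shares its discretization family between
data generation and evaluation, and real skulls, electronics, and
anatomical variability are all richer than the model. Those are inherent
limits of a synthetic study, shared with the modelling approach the
package implements.

## Known limitations

* The constraint tables are internally inconsistent in places (documented
  above); the package picks the reading that satisfies the quantitative
  anchors and exposes everything in an editable config.
* Grid convergence of individual capacitances is first-order; the 64²
  training grid is self-consistent but not converged in absolute value.
* The Picard-elbow default rank for the pseudoinverse is conservative on
  this operator.
* Batch normalization degenerates on batches of size 1; the trainer skips
  such remainder batches.
* Training reproducibility is bit-exact only for a fixed BLAS threading
  configuration.
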