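---
title: "Shape-prior-guided sinogram inpainting: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-prior-guided sinogram inpainting: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Parallel-beam X-ray computed tomography measures line integrals of an
attenuation map $f(x,y)$,

$$R(\theta, r) = \iint f(x,y)\,\delta(x\cos\theta + y\sin\theta - r)\,dx\,dy,$$

collected as a sinogram over a half turn. In limited-angle acquisitions a
*contiguous* block of angles — here between 5% and 95% of the arc — is
never measured, which makes the inverse problem severely underdetermined
and fills reconstructions with wedge artifacts. This package addresses the
industrial inspection setting where the specimen's geometry is known in
advance (CAD drawings; here, circle specifications standing in for bead
cross-sections): the known shapes are rendered into the sinogram domain
and used to fill the missing angular block *before* reconstruction, so
cheap analytic or lightly iterative methods can be used afterwards.

Three families of inpainters share one interface:

* deterministic prior replacement (`inpaint_cad`, optionally with the
  per-angle rescaling described below) and per-detector-bin linear
  interpolation across the gap (`inpaint_linear`);
* U-net regressors trained with an L1 loss (`train_unet_baseline`), with
  or without the prior channel;
* the main method: a conditional adversarial network (`train_gan`,
  pix2pix-style) whose generator maps the three-channel stack
  {masked sinogram, prior sinogram, missing-block mask} to the full
  sinogram and whose discriminator judges 16×16 sinogram patches given
  the prior channel.

## Measurement model

`forward_project()` discretizes the transform ray-by-ray: the ray of each
(angle, detector) pair is walked with unit step and the image sampled by
bilinear interpolation. `back_project()` scatters with the identical
weights, making the pair an exact adjoint (verified to float rounding in
the tests) — the property SIRT needs to converge. Conventions: angles
$\theta_i = i\pi/n$ half-open in $[0, \pi)$, unit detector spacing centred
on zero, image centre at $((H-1)/2, (W-1)/2)$ in 0-based coordinates.

For an object fully inside the field of view the per-angle total
$\sum_r R(\theta, r)$ is a constant (mass conservation). This motivates
the prior rescaling (`scale_prior_columns`): each prior row is multiplied
so its sum equals $T_{\mathrm{ref}}$, the mean per-angle total over the
*observed* angles of the measurement. $T_{\mathrm{ref}}$ is a mean rather
than a per-angle interpolation — the object is assumed fully visible, so
the observed totals already estimate the constant.

## Shape priors

A prior is a list of circles (centre, radius, optional density).
Attenuations are usually unknown from CAD data, so rasterization draws
each unknown density uniformly from $[0.5, 1.5] \times$ the nominal
object attenuation — a symmetric multiplicative band that keeps the prior
on the data's scale while forcing the network not to trust the prior's
amplitude. Circles are filled (boundary + interior), not outlined.
Densities are drawn once per slice with a recorded seed, not re-drawn per
epoch. When the prior must be *recovered* from a reconstruction rather
than supplied, `find_circles()` provides a circular Hough transform
(Sobel gradients on a smoothed image, gradient-direction voting over a
radius range, perimeter-normalized peaks, sub-pixel centroid refinement);
its round trip against the generating specification is tested to within
2 px for non-overlapping discs of radius ≥ 5 px.

## The conditional adversarial inpainter

The generator is an encoder–decoder U-net: 4×4 convolutions with stride
2, batch-norm (absent on the first stage), leaky ReLU (slope 0.2) in the
encoder and plain ReLU in the decoder, skip connections between mirrored
stages, 50% dropout on the first three decoder stages, and a final
stride-1 convolution to one channel followed by Tanh. At the reference
size (256×256, width 64) the encoder widths are
64-128-256-512-512-512-512-512 and the decoder widths
512-1024-1024-1024-1024-512-256-128; for smaller power-of-two inputs the
depth adapts to $\log_2 S$ and the decoder widths follow the rule
"mirror of the encoder, doubled after the bottleneck stage", which
reproduces the reference list at full depth. A width multiplier scales
every stage for desk-size runs.

The discriminator scores non-overlapping 16×16 patches: each patch passes
through a 64-128-256-512 stack of 4×4 stride-2 convolutions (16→8→4→2→1)
and a final 1×1 convolution with a Sigmoid. Tiling, rather than an
overlapping strided stack, makes each output depend on *exactly* one
16×16 patch, which the tests verify by perturbation. The discriminator
conditions on two channels — sinogram and prior — not the mask: its task
is "given a full sinogram and its prior, is the sinogram real?".

Losses: the discriminator minimizes binary cross-entropy with one-sided
label smoothing (real label $1-\varepsilon$, $\varepsilon = 0.1$); the
generator minimizes the non-saturating $-\log D(G)$ plus
$\lambda \, \mathrm{L1}$ with $\lambda = 100$. The non-saturating form is
used instead of $\log(1 - D(G))$ because the latter has vanishing
gradients exactly where the generator needs them most. Gaussian instance
noise (initial $\sigma = 0.05$ in normalized units, decayed linearly to
zero over the epochs) is added to every discriminator input. Generator
updates are *top-k*: per batch of 8, only the `topk_keep = 2` samples the
discriminator currently scores as most realistic contribute to the
generator gradient. Optimization is Adam, learning rate $2\times10^{-4}$,
betas (0.5, 0.999), 100 epochs at the reference scale. There is no
explicit noise vector: stochasticity enters through dropout only.

Normalization reconciles two requirements — inputs "between 0 and 1" and
a Tanh output in $[-1,1]$: all channels are scaled to $[0,1]$ by the
maximum of the training targets, mapped affinely to $[-1,1]$ at the
network boundary, and inverted on output. The network only ever predicts
the missing block: the output is composed as
`masked + mask * denormalized_prediction`, so observed rows pass through
bit-identically — an invariant asserted for every inpainter.

All randomness (initialization, shuffling, dropout, noise, density draws)
comes from R's RNG under a single seed; with single-threaded BLAS a
training run is reproducible bit-for-bit.

## Synthetic data

`make_bead_phantom()` emulates cross-sections through a tube of glass
beads: 256×256 slices with circles of uniform attenuation 25 on
background 1, Gaussian noise added to the object material only (the
background is a homogeneous medium; σ defaults to 0.5, i.e. 2% of the
object attenuation) and clipped at zero. Circles are placed by rejection
sampling with a non-overlap margin. The generating circle list is
returned as the exact "CAD drawing"; densities are stripped before it is
used as a prior.

One deliberate deviation from a literal square background: a uniform
square extends outside the circle inscribed in the detector span, so its
per-angle total attenuation is *not* constant and the rescaling step's
own assumption fails by a few percent. The default `background_mode =
"disc"` therefore fills the background attenuation only inside the
inscribed field-of-view circle — the configuration a fully-visible
specimen actually presents — and `"full"` remains available. Relatedly,
the benefit of the rescaling step depends on the prior accounting for
(nearly) all attenuating mass: with background 1 the objects-only prior
misses ~20% of the mass and rescaling over-amplifies the object ridges,
which genuinely reverses the CAD-vs-scaled-CAD ordering; with an air
background (the regime of the real bead data, whose surroundings are
air) rescaling improves prior replacement by ~2 dB at every wedge. The
test suite checks that ordering on an air-background dataset.

`add_defects()` punches small background-attenuation holes (defaults: 1–3
per object, radius 2–4 px) strictly inside objects *without* recording
them in the circle list — the prior must stay blind to defects, which is
the premise of the defect-recovery analysis below.

`build_dataset()` assembles per-slice records (phantom, target sinogram,
per-slice random contiguous mask, masked sinogram, raw and rescaled prior
sinograms) with every seed derived from one master seed and recorded in a
JSON manifest; the last 10% of slices form the test split. Datasets are
stored as RDS containers (no HDF5 binding is declared as a dependency);
single images round-trip as 32-bit float TIFF.

What the generator does **not** emulate: beam hardening, scatter,
detector cross-talk, Poisson counting statistics, partially-out-of-view
specimens, and non-circular shapes. Passing tests on these phantoms
demonstrate the machinery and the orderings between methods, not
performance on real scans.

## Reconstruction and evaluation

`sirt_reconstruct()` iterates
$x \leftarrow x + C A^{\mathsf T} R (y - A x)$ with $R, C$ the inverse
row/column sums of the projector, optional non-negativity clamping, and a
tracked row-weighted residual that must not increase (the iteration
aborts if it ever grows 10×). On a small full-data system it is verified
against a dense least-squares solve of the explicitly assembled projector
matrix. `fbp_reconstruct()` ramp-filters each row in the detector
frequency domain (zero-padded, optional Hann apodization) and
backprojects with the adjoint, scaled by $\pi / (2 n_\mathrm{angles})$;
its attenuation calibration is verified on a disc phantom (interior mean
within 10%).

PSNR is $10\log_{10}(\mathrm{peak}^2/\mathrm{MSE})$ with the peak taken
from the *target's* dynamic range by default (a fixed-peak mode exists).
Image-domain PSNRs reported elsewhere often rest on an unstated peak or
normalization convention, so absolute image-domain decibels should be
compared across implementations with caution; orderings are unaffected.
Benchmarks (`run_benchmark`) mask test slices at a fixed start angle
(index 0; dataset construction randomizes starts per slice), score the
sinogram against the target sinogram, and score the image domain against
the SIRT reconstruction *from the full sinogram* — not the phantom — so
the reconstruction error common to both cancels. Whether the sinogram
PSNR should cover only the gap is ambiguous; the package scores the full
sinogram (observed rows are identical by construction, so differences
concentrate in the gap) — a gap-only score would differ by the constant
area ratio.

## Desk-scale study configuration

The test suite and the acceptance script reproduce the *structure* of the
full-scale comparisons at desk scale, chosen once: 64×64 sinograms
(64 angles × 64 detectors), 200 synthetic slices (180 train / 20 test),
30% contiguous missing block for the method comparison, network width
multiplier 4 (i.e. encoder 4-8-16-32-32-32), batch size 8, 20 epochs —
roughly 2000 generator updates, after which the training L1 has
plateaued. The defect study scales the hole geometry with the objects (holes of
radius 1.5–2.5 px inside objects of radius 4–9 px, 1–2 holes per object)
with a 33% missing block: larger holes are already well constrained by
the observed two-thirds of the angles, so their reconstruction error no
longer concentrates — even a defect-blind deterministic fill then shows
ratios below 2 — whereas small holes isolate the gap's contribution.

What this desk-scale study does and does not establish. Robust across
dataset realizations: the prior channel is worth ~8 dB to the U-net
(prior-fed vs prior-blind), both learned prior-fed methods beat linear
interpolation at 30% missing, and zero-filling is the floor. Fragile:
the adversarial-vs-L1-U-net margin. The full-scale comparison
shows the adversarial method far ahead of the L1 U-net; at desk scale
the two sit within 1–3 dB of each other and their order can flip with
the dataset seed — top-k discards six of eight samples from the
generator's L1 gradient, and the adversarial term buys no PSNR at this
size (longer training widens the U-net's lead rather than closing it).
The learning-study test runs at fixed, pre-registered seeds and its
conditions were not selected after the fact; this paragraph is the
honest error bar around it. Absolute decibel values at full scale
require the full-size architecture, 100 epochs and the real bead data,
which the package supports but does not ship.

## Known limitations

* The rotate-free ray-driven projector uses bilinear interpolation; its
  quadrature differs from other toolboxes' projectors, so decibel-level
  agreement with externally reported values additionally depends on the projector
  discretization (the reference implementation the publication cites is
  a different toolbox).
* Training at the full 256×256 / width-64 scale is possible but slow on
  a single CPU (the implementation is GEMM-based R/C++, not GPU code).
* The adversarial inpainter fails to restore internal defects that the
  prior does not encode and the observed wedge only weakly constrains:
  in the defect study its reconstruction error is larger over hole
  pixels than over intact object pixels. The degree of concentration
  depends on training scale — a defect-blind deterministic fill (whose
  non-hole error is nearly zero) concentrates more than a desk-scale
  network whose own fill error is still appreciable; matching the sharp
  hole-localized difference images of full-scale training requires the
  full-width architecture and long training.
* `find_circles()` targets well-separated discs (the bead geometry); it
  is not a general ellipse/blob detector.
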