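---
title: "Multistage background field removal: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multistage background field removal: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mubafire)
```

## The field model

A gradient-echo field map measures the per-voxel off-resonance frequency
`b` (Hz), obtained from unwrapped phase by `b = slope(phi vs TE) / 2pi`
(ordinary least squares over echoes; a single echo reduces to division by
`2*pi*TE`). Inside a region-of-interest mask `m` the field decomposes as

    b = b_dist + b_int

where `b_dist` collects everything generated outside the mask — static-field
inhomogeneity, body and coil loading, air/tissue interfaces — and `b_int` is
the contrast of interest, generated by the susceptibility distribution inside
the mask. Susceptibility sources produce fields through convolution with the
unit dipole, spectrally `D(k) = 1/3 - k_z^2/|k|^2` (main field along `z`,
`D(0) := 0` since susceptibility differences do not determine the spatial
mean). Conversion between susceptibility (ppm) and frequency (Hz) uses
`gamma/2pi = 42.577478518 MHz/T`; at 9.4 T, 1 ppm corresponds to 400.2 Hz.

Any field whose sources lie outside the mask is harmonic inside it. The
removal strategy exploits complementary model classes for `b_dist`:

* **POLF** (first order only): constant offset + linear gradients, fitted by
  least squares in physical coordinates centered on the mask center of mass.
  Higher polynomial orders are not offered; they do not correspond to a
  physical solution of the static-field problem.
* **SPHINX**: real regular solid spherical harmonics `N_lm * r^l * Y_lm`
  evaluated at voxel centers and re-orthonormalized on the masked domain, so
  that expansion coefficients are plain inner products `c_lm = <b|u_lm>`.
* **DIPF**: an exterior pseudo-susceptibility fitted so its dipole-convolved
  field matches the masked data (projection onto dipole fields), solved with
  conjugate gradients on the normal equations.
* **Local stage**: threshold/erode outlier pockets, then a DIPF whose source
  support is the excluded pockets themselves.

The full chain runs POLF, then SPHINX (order 4) on the residual, then DIPF,
then optionally the local stage; the stage backgrounds decompose the input
exactly (corrected = input − sum of backgrounds, to rounding).

## Orthonormalization on a masked domain

Solid harmonics lose orthogonality on a discrete, irregular domain, so they
are orthonormalized with respect to the voxelwise inner product over the
masked voxels. The procedure is Gram–Schmidt in basis order (l ascending, m
from −l to l) with one re-orthogonalization pass per vector (CGS2): classical
single-pass Gram–Schmidt loses orthogonality on near-degenerate masked
domains at order 10, while the second pass keeps the Gram residual near
machine precision (observed ~1e-14, asserted ≤ 1e-8). Each vector is
explicitly normalized after the subtraction step, and the recurrence for a
vector subtracts only projections onto *previously completed* vectors —
subtracting a vector's projection onto itself would annihilate it.

Conventions chosen where several are defensible (all unobservable in the
projected background): the expansion center is the mask center of mass; the
radius is normalized by the largest masked-voxel distance from it, keeping
`r^l` in [0, 1] and the raw basis well conditioned up to the practical
ceiling of order 15; real harmonics are built from associated Legendre
functions in the MATLAB/`pracma` convention, signs unadjusted. The l = 0
constant is built and fitted as well — the expansion used for background
removal starts at l = 1 conceptually, but the constant is harmless (the POLF
stage has already removed offsets and all comparison statistics are
mean-insensitive) and completes the nesting used by the order sweep. A basis
is cached per (mask, order) within a study; its leading columns are exactly
the lower-order basis, so order sweeps are nested projections.

A degenerate raw basis (a vector numerically in the span of its
predecessors, post-subtraction norm < 1e-10 of its original norm) raises an
error naming the offending (l, m).

## The dipole filter

DIPF minimizes `||m·(b − c·(chi_ext * d))||^2 + lambda·||chi_ext||^2` over a
pseudo-susceptibility supported outside the mask, with `c = gamma/2pi ·
B_base` and `chi_ext` dimensionless inside the solver (reported in ppm).
`lambda = 500` is stated in that convention, where it is a very mild
ridge — solving in Hz-per-ppm units instead would make the same number
dominate the fit and cripple the filter (we verified: exterior-source removal
degrades from <1% to ~30% residual). The Tikhonov weight is realized as a
hard support restriction (the penalty as printed would act only on values
defined to be zero); a literal soft-penalty mode is available via
`dipf_config(interior = "penalty")`.

Numerical choices: spectral dipole kernel (exact in the continuum, O(N log N))
rather than a truncated real-space kernel; zero padding of 1/8 of the matrix
per side, with pseudo-susceptibility allowed in the padded margin by default
(`allow_pad_sources`); CG initialized at zero, no preconditioner, a fixed
iteration count (default 50) instead of a stopping tolerance. The data-term
norm is recorded per iteration and is non-increasing after the initial
transient. CG at a fixed iteration count is exactly scale-equivariant but
additive only up to its own convergence tolerance — the linearity test
asserts both at their attainable levels.

Convergence depends on source geometry: compact sources near the mask are
recovered to <1% residual in 50 iterations, while a single-voxel source
needs ~200 iterations for the same accuracy (CG resolves the strongest
singular vectors first). The acceptance check for exterior-source removal
therefore uses a compact surface-adjacent source, the air-pocket analogue.

## The local stage

Thresholding flags masked voxels with `|b| > n_sigma * sigma(b)` (population
standard deviation of the chain-corrected field inside the original mask;
`n_sigma` defaults to 8, typical range 5–15). Diagonal connection adds, for
every pair of flagged voxels differing by one step in exactly two axes, the
two face-bridging voxels; for three-axis diagonals the three single-axis
bridges (the natural extension of the two-axis rule). A six-neighbor margin
is then added inside the mask. The refinement runs once, not iterated.
The final DIPF restricts its source support to the excluded pockets and its
fit domain to the remaining mask, removing the spurious dipole halo the
pocket radiates into surrounding tissue; excluded voxels are reported as
missing rather than inpainted, since they do not carry representative data.

## The synthetic phantom and Monte Carlo study

The simulator emulates a brain-like acquisition at 9.4 T: a perturbed
ellipsoid mask (smooth radial wobble, kept clear of the volume edge), a
static susceptibility map with tissue at −9 ppm plus smooth texture bounded
at ±0.2 ppm, vessel-like tubes at −7.9 ppm, ventricle-like blobs at −9 ppm,
exterior at −6 ppm and a few positive pockets (+0.4 ppm, air-like on this
absolute scale) just outside the surface. Per sample it draws a smooth ±0.2
ppm susceptibility variation with a few sharp blobs, a random solid-harmonic
inhomogeneity of orders 1–4 rescaled so its volume maximum is exactly 400 Hz
(no l = 0 term: a global offset is degenerate with the POLF constant), and
Gaussian field noise of 0.3 Hz. The observed field follows

    b_obs = (1 + b_inh/(gamma' B_base)) · b_sus + b_inh + noise

with the multiplicative local-field factor entering at relative order 1e-6
(a property test pins its placement). The reference field re-runs the
forward model with the exterior set to the mask-mean internal susceptibility
and removes the masked mean.

Two design points deserve emphasis. First, the forward convolution is
evaluated on susceptibility *differences* (relative to the exterior value;
relative to the internal mean for the reference): a zero-padded FFT applied
to absolute values would add a large artificial "box interface" field from
the volume edge. Second, the phantom is a parametric stand-in for real
anatomy: its texture amplitude and correlation length (0.033 ppm / 1.6
voxels at desk scale) and vessel geometry were calibrated once so the
reference field's masked standard deviation lands at the literature scale of
~6.25 Hz for the full-scale simulation design, then frozen. The phantom does
not emulate realistic cortical folding, skull/CSF layers, or the
high-order surface detail of a segmented brain, so absolute error levels of
surface-sensitive filters (Gaussian, standalone harmonic fit) carry that
caveat.

The routine study uses the desk-small preset: a 72 × 80 × 56 matrix,
n = 10 seeds, one phantom per study with per-sample randomization, Gaussian
sigma 2 voxels (the full-scale value 4 scaled by the linear matrix ratio).
These sizes keep a full comparison study around ten minutes on one CPU;
the full-scale 138 × 162 × 106 preset is provided and produces the same
qualitative picture (single-sample check: standalone DIPF 1.42 Hz vs chain
1.42 Hz mean L1).

## Evaluation

The comparison metric is the masked mean absolute deviation from the
reference, `L1 = (1/n) Σ |b_corr − b_ref|`, with the reference mean-free by
construction. The corrected map is mean-removed by default (a constant is
not determined by background removal); `demean = "reference"` keeps any
offset in the score — on the study both give identical results to three
decimals because every filter leaves a near-zero masked mean. Sweep tables
normalize the error by the masked standard deviation of the reference, a
dimensionless and monotone-equivalent choice. Histogram summaries use
fixed-width bins in Hz; standard deviations use the population convention
throughout. Wall-clock times are recorded in reports but never asserted.

## A finding on the standalone dipole filter

On this simulation a well-converged dipole filter is essentially as accurate
as the full chain: 50 CG iterations with the spectral kernel remove the
order ≤ 4 harmonic inhomogeneity to ~0.25% residual, so standalone DIPF and
the chain differ by only ~0.005 Hz in mean L1 (the chain is marginally
*worse*, because the order-4 harmonic projection absorbs a sliver of true
internal contrast). Historical full-scale comparisons report standalone
dipole filtering substantially worse than the multistage chain; we tested
and excluded, as explanations within this implementation, the
regularization-unit convention, confining sources to the measured volume,
offset handling in the metric, and matrix scale. The reported gap appears to
be a property of less-converged or differently-conditioned solvers — the
multistage design remains valuable exactly when the dipole fit is expensive
or poorly converged, which is the regime those comparisons describe. The
package reports what its own solver achieves; the corresponding comparison
checks are asserted at their literature levels and fail visibly rather than
being weakened.

## Known limitations

* Phase unwrapping, brain extraction and coil combination are out of scope;
  inputs must be unwrapped phase or field maps plus a mask.
* Harmonic orders above 15 are refused (conditioning of `r^l` on discrete
  domains).
* The local stage excludes voxels permanently; small anatomical structures
  overlapping an exclusion pocket are reported as missing.
* The simulator's anatomy is parametric; quantitative agreement with
  template-based full-scale studies is expected in ordering and magnitude,
  not to printed precision.
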