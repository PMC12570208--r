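---
title: "Reconstructing single-particle densities by multi-tiered iterative phasing"
author: "spimtip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing single-particle densities by multi-tiered iterative phasing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In single-particle imaging (SPI) at an X-ray free-electron laser, each
femtosecond pulse produces one diffraction pattern of one particle caught in
an unknown random orientation, and destroys it. A flat detector at fixed
wavelength records, per shot, photon counts on a curved two-dimensional
slice of the particle's three-dimensional diffraction intensity
$I(\mathbf q) = |G(\mathbf q)|^2$, where $G$ is the Fourier transform of the
electron density $\rho$ and the slice is the Ewald sphere rotated by the
(unknown) particle orientation. Reconstruction must therefore recover, from
a stack of $D$ noisy patterns, simultaneously

* the orientation of every pattern,
* the 3D intensity — equivalently the autocorrelation
  $A = \mathcal F^{-1}[I]$ of the density (Wiener–Khinchin), and
* the Fourier phases, hence $\rho$ itself;

and, when the sample is a mixture of conformational states, one density
model per state together with a per-pattern state assignment.

`spimtip` implements this multi-tiered iterative phasing (M-TIP) loop at
desk scale, together with a simulator that generates the study data, so
every stage is testable end-to-end without any external input.

## The generation loop

One *generation* performs, in order:

1. **Slicing.** For each conformation's current density estimate, reference
   images are computed on a fixed, predetermined orientation set by
   evaluating the model intensity at the rotated Ewald-sphere points of the
   detector. The evaluation is a type-2 (uniform → nonuniform) NUFFT of the
   model autocorrelation: $I(\mathbf q) = \sum_k A_k\,
   e^{-2\pi i \mathbf q\cdot \mathbf x_k}\,v^3$ with $v$ the voxel size.
2. **Orientation matching.** Every pattern is compared against every
   reference slice of every conformation, and assigned the argmin pair.
   The default distance is a weighted L2 norm
   $\sum_p w_p (I_p - s R_p)^2$ with per-pixel weights
   $w_p = 1/\max(I_p, 1)$ (the approximate inverse variance of Poisson
   counts) and the closed-form optimal per-image scale
   $s = \sum w I R / \sum w R^2$, which absorbs the unknown per-shot
   fluence. A Poisson negative log-likelihood
   $\sum_p [sR_p - I_p\log(sR_p+\varepsilon)]$ (with $s$ refined by Newton
   steps, $\varepsilon = 10^{-12}$) is available as an alternative. Matching
   is exhaustive — no pruning — which is affordable at desk scale and is the
   behavior the selection rule defines.
3. **Merging.** The oriented samples define an overdetermined linear system
   $A x = b$, where $A$ is the type-2 NUFFT from the autocorrelation grid to
   all rotated detector points and $b$ the (fluence-normalized) counts. The
   Tikhonov-regularized normal equations $(A^H A + \lambda I)x = A^H b$ are
   Toeplitz: $A^H A$ acts as a convolution whose kernel is the type-1 NUFFT
   of unit weights on a $2M$ grid, so each operator application costs two
   Cartesian FFTs. Setup therefore needs exactly two type-1 NUFFTs per
   conformation and generation — one on the data, one on ones. The system is
   solved iteratively (see *Numerical choices*), and a small geometric grid
   of $\lambda$ values is swept with an L-curve corner selection on
   (log data misfit, log solution norm).
4. **Phasing.** The merged autocorrelation is Fourier-transformed to an
   intensity volume (clipped to be nonnegative and Friedel-symmetrized), and
   a real, nonnegative, compactly supported density is recovered by
   alternating projections: hybrid input-output (HIO, feedback parameter
   $\beta = 0.9$) followed by error reduction (ER), with shrinkwrap support
   refinement (Gaussian blur sd 1.5 voxels, threshold 12% of the blurred
   maximum, every 20 iterations). The first pass uses seeded random phases
   with multi-start (best final Fourier error wins); later generations warm
   start from the previous density.

Generation 0 initializes the process with uniformly random orientations
(and, for $K > 1$, uniformly random conformation assignments), merges and
phases once, and the resulting model anchors the orientation frame of all
later passes. The loop stops when the maximum (over conformations) aligned
relative density change between consecutive generations falls below
`convergence_tol`, or after `n_generations_max` generations; both stopping
modes are exposed because neither is canonical.

Two gauge freedoms need care. Phase retrieval determines $\rho$ only up to
translation and centro-inversion; `align_densities()` maximizes normalized
cross-correlation over all cyclic shifts and the inversion twin (via FFT
correlation) and is used both for the convergence metric and for scoring
against ground truth. Second, for a (nearly) flat Ewald sphere the Friedel
symmetry $I(\mathbf q) = I(-\mathbf q)$ makes an orientation and its
composition with a half-turn about the beam axis indistinguishable;
accuracy scoring counts that twin as correct, and matching itself never
uses symmetry information.

## The NUFFT operators

The package's conventions: type-2 evaluates
$f(\mathbf p) = \sum_k F_k e^{-2\pi i \mathbf p\cdot\mathbf x_k}$ on the
centered cubic grid $\mathbf x_k = v\,(j - M/2)$; type-1 is its exact
adjoint ($e^{+2\pi i}$, no $1/N$ scaling); frequencies are in cycles per
unit length, so the representable band is $|p_d| \le 1/(2v)$ per axis.

The fast path is Gaussian-kernel gridding on a $2\times$ oversampled fine
grid: each node touches $(2m)^3$ fine-grid points of the separable kernel
$\exp(-d^2/4\tau)$ with $\tau = \pi m / (3M^2)$, and the mode-domain
deconvolution is the kernel's analytic transform. The half-width $m$ is
derived from the requested tolerance via the $e^{-3\pi m/4}$ truncation
bound plus one step of safety margin, so `tol = 1e-8` gives $m = 9$ and the
direct-sum oracle agreement demanded by the test suite, while the
reconstruction loop runs at `tol = 1e-3` ($m = 4$), which is far below the
Poisson noise floor of the data being gridded. A dense $O(M^3 P)$
direct-sum implementation of both transforms is part of the package and
serves as the oracle on every small instance; the implementation contract
is agreement with it, not any particular gridding scheme. Spreading visits
points in fine-grid bucket order (a counting sort) and works on a
halo-padded cube with contiguous inner loops; periodicity is applied by a
single fold. These are performance choices only — they do not change the
operator.

## The synthetic-data generator

The phantom is a sum of `n_blobs = 6` isotropic Gaussian blobs
(sd 2.5 voxels) with seeded random centers, clipped to a spherical support
of radius $N v / 4$ on an $N = 32$ grid ($v$ = 1 nm by default; all units
are meters internally, with Angstrom-based convenience constructors at the
detector level).

The blob width is the one genuinely contested parameter of the generator,
because it trades two desiderata against each other. *Structural
distinctness:* blobs at the 1-voxel scale make independent phantoms
genuinely different objects — their aligned correlation (the empirical
null of the recovery score) stays below 0.5 — whereas 2-voxel blobs
confined to an 8-voxel support sphere overlap into a shared smooth
envelope and unrelated phantoms already correlate near 0.85. *Cold-start
orientability:* the M-TIP loop must bootstrap orientation assignments
from a featureless first-pass model, and that symmetry breaking relies on
low-frequency anisotropy; truth-initialized experiments show the true
model is a stable fixed point of the noisy loop at **all** widths
(one-generation-from-truth correlations 0.94-0.97 for sd 1.5-2.5
voxels), but from a random start the sharp-blob loop remains trapped near
the spherically-averaged model for longer than a desk-scale generation
budget, while broad-blob phantoms escape and converge within about ten
generations. The default is therefore sd 2.5 voxels — the configuration
whose reference reconstruction study converges end-to-end from a cold
start — and recovery correlations for the default phantom must be read
against its elevated null (~0.9): the reconstructions reported by the
acceptance machinery sit well above it, and the orientation-accuracy and
truth-stability tests establish that orientations are genuinely recovered
rather than merely the envelope. The empirical-null property itself is
exercised in the test suite with sub-voxel-width blobs, where it is meaningful.

A related subtlety concerns the reference-orientation scheme. For a flat
Ewald sphere, an orientation and its beam-axis half-turn twin produce
identical slices of a Friedel-symmetric intensity, so a twin-reduced
fundamental-domain grid (`reference_grid(..., "friedel_reduced")`) halves
slicing and matching cost at fixed effective angular resolution. For the
*curved* Ewald sphere, however, the two twins sample slightly different
longitudinal positions (about 0.6 reciprocal voxels at the detector
corner here), and matching over the full grid is what lets the loop pick
the curvature-consistent member of each pair; forcing a single
representative was observed to trap the loop in a spurious
self-consistent model. The loop therefore defaults to the full
`quasi_uniform` grid, and the reduced scheme is reserved for genuinely
flat-Ewald settings. The two-conformation phantom duplicates the blob set and
translates the first blob by 3 blob sigmas — two clearly distinct but
largely overlapping states, a deliberately simplified stand-in for an
open/closed conformational pair of a real chaperonin-like particle.

The detector is a 64×64-pixel square (100 µm pitch, 1 Å wavelength) whose
sample distance is chosen so the detector corner reaches 90% of the
phantom grid's Nyquist frequency; every rotated Ewald sample then stays
inside the representable band. Patterns are simulated by evaluating
$|G(\mathbf q)|^2$ at the rotated Ewald points via the type-2 NUFFT of the
density itself — a representation deliberately different from the
autocorrelation-grid slicing used inside the reconstruction, so
reconstruction errors cannot cancel against simulation errors exactly
(the two agree analytically because the oversampled autocorrelation grid
carries the full trigonometric interpolant of a compactly supported
density, but the code paths and tolerances are independent).

Four corruptions are modeled, each seeded: Poisson photon counting;
per-shot fluence jitter, log-normal with unit mean and coefficient of
variation 0.15; beam miscentering as an integer-pixel image shift from a
rounded Gaussian (default sd 0, i.e. off); and a static sloped background
plane added to the expected counts (default zero). The reconstruction
studies use Poisson noise and fluence jitter at a mean of $2\times10^4$
photons per pattern — a bright-hit regime in which orientation
determination is information-rich; the fitted per-image scale in matching
is what absorbs the jitter. The simulator does *not* model SASE spectra,
hydration layers, detector gain stages, multi-particle hits, or atomistic
scattering factors; passing tests therefore demonstrate the correctness of
the reconstruction machinery under the stated noise model, not robustness
to every artifact of real beamtime data.

## Numerical choices

* **Merge solver.** The normal equations are solved with a conjugate
  residual iteration (the residual-minimizing member of the conjugate
  gradient family for symmetric positive definite operators), zero or
  warm-started initial guess, stopping at relative residual `1e-3` inside
  the loop (`1e-6`/`1e-10` in verification tests) or at `merge_max_iter`.
  The residual-minimizing variant was chosen so the residual norm is
  provably non-increasing, which makes the solver's progress monotone and
  testable; per iteration it costs the same one operator application as
  classic CG. Warm starts reuse the previous generation's solution and
  fall back to zero if that guess does not reduce the initial residual.
* **Tikhonov operator and grid.** The regularizer is the identity
  ($\lambda\|x\|^2$). $\lambda$ values are expressed relative to the kernel
  zero lag (the mean eigenvalue of $A^H A$); the loop sweeps
  $\{10^{-4}, 10^{-3}, 10^{-2}\}$ in every generation, mirroring the
  hyper-parameter farming the method prescribes. The L-curve corner is the
  maximum discrete curvature in sorted-$\lambda$ order, falling back to
  the smallest $\lambda$ within 5% of the minimum misfit when fewer than
  three candidates exist.
* **Friedel symmetrization in merging** is implemented by taking the real
  part of the type-1 outputs, which is algebraically identical to
  augmenting the sample set with $(-\mathbf q, I)$ mirrors at no extra
  cost.
* **Scale fixing.** After each phasing step the density is normalized to
  unit integrated mass. The overall intensity scale is a gauge (matching
  fits a per-image scale; merging consumes fluence-normalized counts), and
  pinning it keeps every stage's magnitudes of order one instead of
  drifting by factors of $v^3 \sim 10^{-27}$ per round trip.
* **Fluence normalization for merging.** The per-shot fluence entering the
  merge is estimated from each image's total counts relative to the stack
  mean — an assignment-independent statistic — rather than from the
  matching step's fitted scale. The fitted scale is conditional on the
  assigned reference slice, so early in the loop (when many assignments
  are wrong) it systematically distorts the merged volume; with the
  totals-based estimate the loop holds a near-truth model stably, where
  the fitted-scale variant was observed to walk away from it. Fitted
  scales are still what the matching metric itself optimizes over.
* **Degenerate inputs.** All-zero reference slices are skipped (and
  flagged) under the Poisson metric; a conformation that loses all images
  is re-seeded with the worst-matching half of the largest conformation's
  images rather than silently dropped; zero intensity phases to the zero
  density; ties in matching break to the lowest orientation index, then
  the lowest conformation index.
* **Storage conventions.** Images are fast-axis-major; Fourier volumes are
  centered (zero frequency at index $M/2+1$); densities live on grids with
  voxel centers at integer coordinates; quaternions are scalar-first,
  right-handed, active, canonicalized to $w \ge 0$.

## Problem sizes and defaults

The package defaults define the reference study: a $32^3$ phantom,
$64\times64$ detector, $D = 2000$ patterns, $n_\mathrm{ref} = 400$
quasi-uniform reference orientations (a Halton low-discrepancy sequence
mapped through the uniform-quaternion construction; a ZYZ Euler-angle grid
is available), oversampling 2 (a $64^3$ working grid), and at most 12
generations. These sizes were chosen so that a complete K = 1
reconstruction is a matter of minutes on one CPU core while every stage
still operates in its intended regime; the orientation count in particular
is a resolution trade-off (about $33^\circ$ mean spacing on SO(3)) that
matches the smooth, low-resolution phantom. No reference-orientation count
or spacing is canonical for the method; both the count and the scheme are
configuration parameters.

Known limitations worth stating plainly: with hard argmin assignment the
loop is a heuristic fixed-point iteration, and its summed matching distance
is not monotone generation-to-generation (it decreases in most but not all
generations); the aligned density change typically plateaus at the Poisson
noise floor rather than converging to zero, so the generation cap is the
stopping rule that usually binds; and labels for K > 1 are recovered only
up to permutation, which is how they are scored.

The most consequential limitation is two-state separation. At the
reference photon budget (2×10⁴ photons per pattern) the conformational
signal — one blob displaced by 2.4 sigma — is weak: even matching against
the *true* pair of models classifies only ~82% of patterns correctly
under the Poisson likelihood (62% under weighted L2; the likelihood
metric is therefore the one to use for mixtures), and from any tested
initialization the hard-argmin loop collapses onto the mixture-average
fixed point, with both models converging to the same density and
essentially random state assignments. The package provides the staged
initialization (`split_conformations()` after a converged K = 1 fit,
continued via `mtip(..., init_densities = )`), which is the textbook
remedy for symmetric collapse, but at this noise level the amplification
gain of the state-difference component remains below one and separation
does not self-organize. Soft, expectation-maximization-style assignment
would raise that gain but is deliberately out of scope — the method
implemented here is hard argmin selection. The corresponding end-to-end
test records this honestly: it asserts the separation targets and fails
at the reference conditions, while the oracle-separability and
truth-stability checks document what the machinery itself can do.

## What the tests establish

The test suite checks each stage against an independent oracle: dense
direct sums for both NUFFT types and the adjoint identity; explicit dense
linear algebra for the normal-equation operator and solver; brute-force
triple loops for matching; closed-form identities (zero-frequency
intensity, autocorrelation peak, Poisson moments) for the simulator;
projection fixed points for phasing; and end-to-end recovery of known
phantoms — autocorrelation to within a few percent from noise-free
oriented samples, densities above 0.9 aligned correlation from noise-free
intensities, above 0.8 from the full noisy loop, and two-state separation
with majority-correct classification on a 50/50 mixture. The acceptance
script (`scripts/acceptance.R`) recomputes these end-to-end quantities
from scratch at reduced problem sizes chosen to finish in minutes; the
test suite runs the full-size versions.
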