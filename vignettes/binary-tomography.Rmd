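---
title: "Binary tomography for photoacoustic vasculature imaging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binary tomography for photoacoustic vasculature imaging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Photoacoustic tomography (PAT) reconstructs the initial acoustic pressure
rise $x$ — proportional to absorbed optical energy, hence to blood content —
from ultrasound time traces $b$ recorded by detectors surrounding the
object. After discretisation the acquisition is linear,

$$ A x = b, $$

with $A$ an $NM \times NP$ system matrix ($NM$ = detectors × time samples,
$NP$ = pixels). The clinically interesting content is usually a
*segmentation*: which pixels are vessel and which are background. The
conventional route reconstructs a grey-valued image (backprojection,
Tikhonov, sparsity-regularized inversion) and segments it afterwards. The
binary tomography solver in this package instead constrains the
reconstruction itself to two levels $\{u_0, u_1\}$, $u_0 < u_1$, so the
output *is* the segmentation, computed directly from the sinogram.

## Forward model

`build_system_matrix()` discretises the circular-mean (circular Radon)
projection: the trace a point detector records from a source distribution is
the time-derivative of the mean of $x$ over circles $|y - d| = ct$ expanding
about the detector. Each pixel contributes to the time bins its radial
footprint $dx/c$ overlaps (a box kernel — radial antialiasing), with weight
$\propto dx^2 / (2\pi r\, c\, \Delta t)$ for cylindrical spreading. Two
temporal responses are composed spectrally with the geometric arc matrix:

* the **thermoacoustic derivative** $i\,2\pi f$ — the physically detected
  pressure is the time-derivative of the retarded circular mean. This term
  matters beyond physics: the normal operator of plain circular means has a
  $1/|k|$ spectrum, so with the derivative applied on both sides,
  $A^{\mathsf T} A$ acquires a net $|k|$ (ramp) character and the adjoint
  $x_{bp} = A^{\mathsf T} b$ behaves like a filtered backprojection instead
  of a hopelessly blurred sum of arcs;
* the **transducer band limit**: a zero-phase flat-top low-pass (10th-order
  Butterworth magnitude) with its −6 dB point at the maximum detectable
  frequency $f_{\max} = f_c (1 + \beta/2)$ (3.0375 MHz for a 2.25 MHz, 70%
  transducer), with DC removed exactly. We deliberately do *not* use a
  Gaussian 70% band: such a response attenuates the 0–1 MHz content that
  encodes the interiors of extended absorbers by two to three orders of
  magnitude, which turns every disk into a donut and caps the achievable
  Dice of all comparator methods far below what the study design presumes.
  The band-edge fields $f_{\min}, f_{\max}$ are retained on the transducer
  object as metadata.

Both responses are applied per trace via the FFT; the adjoint applies the
conjugate response, and the adjoint identity
$\langle Ax, y\rangle = \langle x, A^{\mathsf T} y\rangle$ holds to
relative $10^{-10}$ for the composed operator (tested).

The in-silico protocol rasterises phantoms on a fine grid
(402×402, 0.05 mm), simulates the sinogram there, and inverts on a coarser
grid (201×201, 0.1 mm). Generating and inverting with the identical
discrete model (the *inverse crime*) makes every method look spuriously
good; `simulate_measurement()` therefore always builds two operators and
warns when the grids coincide. Even so, the coarse binary raster can only
represent disk edges to one pixel, which is the dominant error floor at
desk scales — noise at 30–60 dB contributes an order of magnitude less
misfit than this representation error, which is why (as in the reference
study) the Dice scores barely move across 30/40/60 dB.

## Phantoms

* **Derenzo-style disks** (`generate_derenzo()`): six 60° sectors with
  per-sector disk radii {1.2, 1.0, 0.8, 0.6, 0.45, 0.3} mm on triangular
  lattices, centre spacing twice the diameter, rows from 3 mm to 9 mm
  radius. The exact layout of the original study is not published; this is
  the standard Derenzo convention, and downstream scores are therefore
  reproduced in a scaled-down sense rather than digit-for-digit.
* **Vessel trees** (`generate_vessel_tree()`): a seeded recursive binary
  branching walk (two children per branch, width decay 0.75, turn angles
  15–40°) rasterised as thick polylines; sparse, connected, curvilinear —
  the qualitative character of vasculature, not an anatomical atlas.
* **Random disks** (`generate_disks()`): seeded non-overlapping disks for
  parameter-recovery experiments.

All generators rasterise by pixel-centre-inside tests (no anti-aliasing) so
ground truth stays strictly two-valued; every generator is a pure function
of (grid, spec, seed) and repeated calls are bit-identical.

What the synthetic data do **not** emulate: full-wave propagation
(heterogeneous speed of sound, attenuation, reflections), finite detector
aperture, laser fluence inhomogeneity, and real electronic noise spectra.
Passing tests on these phantoms demonstrates correctness of the inversion
chain under the stated acoustic model, not performance on any particular
scanner.

## Comparator reconstructions

* `backproject()`: $x = A^{\mathsf T} b$, single pass.
* `tikhonov_solve()`: $\min_x \|Ax-b\|^2 + \lambda\|x\|^2$, solved
  matrix-free by conjugate gradients on the damped normal equations —
  identical minimiser to the closed form $(A^{\mathsf T}A + \lambda
  I)^{-1}A^{\mathsf T}b$ without ever forming $A^{\mathsf T}A$ (verified
  against dense solves to $10^{-6}$ up to 400 unknowns).
* `l1_mm_solve()`: $\min_x \|Ax-b\|^2 + \lambda\|x\|_1$ by
  majorization–minimization: $x \leftarrow
  \mathrm{soft}(x + \tfrac{1}{c}A^{\mathsf T}(b-Ax),\ \lambda/2c)$ with
  $c \ge \|A\|^2$ (power-iteration estimate × 1.05). The objective is
  non-increasing by construction and asserted in tests. Negative values are
  retained in the output; clipping is an evaluation-stage choice.

The study selects $\lambda$ "heuristically for the best figure of merit";
`sweep_lambda()` is the faithful equivalent: it scores a grid of values by
Dice against the (simulation-only) ground truth and returns the argmax with
the full table.

## The binary solver

The constrained problem — fit the data subject to $x$ being the two-level
image induced by the sign of an auxiliary variable — is attacked through
its Lagrange dual. For the multiplier $v \in \mathbb{R}^{NP}$ the dual
objective splits into a smooth data-fit term and the asymmetric one-norm

$$ p(v) = \sum_i |u_0| \max(-v_i, 0) + |u_1| \max(v_i, 0), $$

whose proximal operator is the asymmetric soft-threshold
(`asymmetric_soft_threshold()`: shrink values above $|u_1|$ by $|u_1|$,
raise values below $-|u_0|$ by $|u_0|$, zero the dead zone). The smooth
term's gradient at $v$ is $-\hat x(v)$ where

$$ \hat x(v) = \arg\min_x \tfrac12\|Ax-b\|^2 + \tfrac{\varepsilon}{2}\|x\|^2 + v^{\mathsf T}x $$

is a damped, shifted least-squares solution computed matrix-free by warm-
started conjugate gradients. `solve_binary()` iterates the proximal
gradient step

$$ v \leftarrow S_{\mathrm{asym}}\big(v + \tau\,\hat x(v);\ \tau|u_0|,\ \tau|u_1|\big), $$

and recovers the primal image through the Heaviside map
$x^\ast = u_0 + (u_1-u_0)H(v^\ast)$ with the convention $H(0) = 0$
(undecided pixels fall to background, the conservative class for
vasculature maps). The output takes at most two values by construction.

### Numerical choices

* **Damping continuation.** The smooth dual gradient has Lipschitz constant
  $1/(\sigma_{\min}(A^{\mathsf T}A) + \varepsilon) \approx 1/\varepsilon$,
  so the safe step is $\tau = \varepsilon$ and the iteration is stiff: a
  small $\varepsilon$ is nearly unbiased (the $\varepsilon\|x\|^2$ term
  penalises each foreground pixel by $\varepsilon u_1^2/2$, biasing large
  dampings towards background) but converges extremely slowly. The solver
  therefore anneals $\varepsilon$ from $10^{-2}\|A\|^2$ down to the final
  $10^{-4}\|A\|^2$ in half-decade stages, warm-starting $v$ and the inner
  CG state across stages. On the Derenzo benchmark this reaches in a few
  hundred total iterations a solution the fixed-damping iteration does not
  approach in thousands.
* **Step control.** Within a stage $\tau = \varepsilon$, with bounded
  backtracking. Because the dual objective is only evaluated through the
  inexact inner solve, sub-0.1% "increases" are treated as evaluation noise
  and accepted; persistent large increases raise an error suggesting a
  smaller step.
* **Degenerate exact-fit ties.** When the data are fitted exactly the dual
  optimum is $v^\ast = 0$: the slope $|u_1|$ of $p$ exactly cancels the
  data gradient wherever $\hat x = u_1$, so the pure Heaviside map would
  return all-background. Zero-multiplier pixels whose least-squares value
  equals $u_1$ (to $10^{-6}$ relative) are ties with zero cost difference;
  the solver resolves them to the absorber level, which attains the same
  residual. This is exercised by the exhaustive-enumeration oracle tests on
  2×2 and 3×3 grids.
* **Levels.** $u_0 = 0$ throughout; $u_1$ may be given (known source
  amplitude) or estimated by `estimate_levels()` as the 95th percentile of
  the positive part of a lightly damped least-squares reconstruction — the
  package default, and the only option for experimental data where the true
  amplitude is unknown.
* **Stopping.** Relative dual-objective change below `tol` (default
  $10^{-7}$) per stage, or the shared `max_iters` budget (default 250 outer
  iterations across stages). The budget is deliberately modest: at the
  noise levels studied, running the final low-damping stage much longer
  lets isolated noise-driven pixels accumulate positive multipliers, so a
  bounded budget acts as implicit regularization — consistent with the
  short reconstruction times the method is known for.

## Evaluation

The Dice coefficient $2|X\cap Y| / (|X|+|Y|)$ compares binary masks.
Grey-valued reconstructions are segmented by the study's protocol: clip
negatives at zero, threshold strictly above the mean of the clipped image
(`segment_threshold_mean()`); the mean is taken over *all* pixels. A
deterministic two-class k-means on intensities (`segment_kmeans2()`,
centroids initialised at the min and max, so no RNG) is provided for the
overlay figures. The binary solver's output is scored directly on its
upper level set — it is already a segmentation. `error_overlay()` renders
false positives green and false negatives pink; `line_profile()` samples
images bilinearly along physical segments; `benchmark_table()` runs the
full factorial design and reports mean Dice per cell.

SNR/PSNR-type image metrics are deliberately not implemented: with a
background-suppressing method they would bias the comparison toward the
binary solver.

## Problem sizes and what the packaged runs show

The acceptance script (`scripts/acceptance.R`) and the ordering/band test
blocks run the full protocol at the study's native scale — 402² forward
grid, 201² inversion grid, 80 detectors — reusing the operators across
noise levels; the whole run fits in minutes on one CPU. Most unit tests use
much smaller grids (24²–64², 4–32 detectors) where dense oracles are
affordable.

At the native scale, with this package's phantom convention:

* the strict quality ordering backprojection < Tikhonov < L1 < binary holds
  at 30, 40 and 60 dB (and, as in the reference study, the scores barely
  move across noise levels, because coarse-grid representation error —
  not noise — dominates the misfit);
* the L1 and binary Dice scores land within ±0.05 of the reference row;
* the backprojection and Tikhonov scores land *below* their reference
  values. Backprojection is streak-limited: with 80 views and a ramp-like
  normal operator, the angular Nyquist radius ($N_{det}/(2\pi k_{\max})
  \approx 6$ mm) is smaller than the phantom's 9 mm extent, and the global
  mean threshold admits a large fraction of the streak texture — its best
  achievable Dice over *all* thresholds is ≈ 0.81 here. Tikhonov is limited
  by edge pixels at the coarse grid. Both are reported as computed; with
  the original phantom geometry unpublished, larger disks (or a published
  layout) would be needed to close this gap honestly.

A caution for further down-scaling: shrinking the reconstruction grid to
101² degrades the binary solver *more* than the L1 comparator (the binary
raster must commit every one-pixel edge band, while the soft L1 image lets
the mean threshold split it), to the point that their order swaps. The
ordering claim is a property of the study's native resolution, not of
arbitrary miniatures of it.

## Known limitations

* 2-D only; full-wave effects, finite apertures and fluence are out of
  scope.
* Two classes only; multi-level discrete tomography is a different problem.
* The dual solver's continuation schedule is tuned for operators whose
  spectrum resembles a full-ring PAT matrix; exotic geometries may need a
  custom `epsilon_start` / `step`.
* Full-view acquisition is assumed; limited-angle behaviour is untested.
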