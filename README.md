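# binpat — binary tomography for photoacoustic imaging

Photoacoustic tomography (PAT) images vasculature by reconstructing the
initial pressure rise `x` from ultrasound traces `b` recorded on a detector
ring, a linear inverse problem `A x = b`. What one usually wants from such
an image is a segmentation — vessel vs background — and the conventional
two-step route (reconstruct a grey image, then segment it) loses
information at both steps.

`binpat` implements **binary tomography** for 2-D PAT: the reconstruction
is constrained to two levels `{u0, u1}` from the start, so the solver
returns a segmentation computed directly from the sinogram. The constrained
problem is solved through its Lagrange dual

```
v* = argmin_v  [ smooth data-fit term ] + p(v),
p(v) = Σ_i |u0| max(-v_i, 0) + |u1| max(v_i, 0)
```

by proximal gradient descent, where the proximal operator of the asymmetric
one-norm `p` is an asymmetric soft-threshold and the smooth term's gradient
is `-x̂(v)`, a damped least-squares solution computed matrix-free. The
primal image is recovered through the Heaviside map
`x* = u0 + (u1 - u0) H(v*)` and is strictly two-valued by construction.

Around the core solver the package provides:

* a sparse circular-Radon system matrix with the thermoacoustic
  time-derivative and a bandlimited transducer response (`build_system_matrix`,
  `forward_project`, `adjoint_project`),
* synthetic Derenzo-style, vessel-tree and random-disk phantoms
  (`generate_derenzo`, `generate_vessel_tree`, `generate_disks`),
* calibrated Gaussian noise (`add_awgn`) and an inverse-crime-avoiding
  simulation driver (`simulate_measurement`),
* the three comparator reconstructions — backprojection, Tikhonov (L2) and
  L1 majorization–minimization (`backproject`, `tikhonov_solve`,
  `l1_mm_solve`, `sweep_lambda`),
* Dice-coefficient evaluation with clip-at-mean and 2-class k-means
  segmentation, FP/FN overlays, line profiles and a factorial benchmark
  (`dice`, `segment_threshold_mean`, `segment_kmeans2`, `error_overlay`,
  `line_profile`, `benchmark_table`),
* file containers (float TIFF + YAML sidecars for images, TSV + YAML for
  sinograms), pipeline commands (`cmd_simulate`, `cmd_reconstruct`,
  `cmd_evaluate`, `cmd_benchmark`) and a thin CLI at `inst/cli/pat`.

## Worked example

The in-silico study design: a 1 kPa Derenzo-style phantom on a 20.1 mm
field of view, 80 detectors on a 22 mm ring, 512 samples at 50 ns, a
2.25 MHz / 70% transducer, 30 dB data SNR; forward model on a fine 402²
grid, inversion on a coarse 201² grid (avoiding the inverse crime). The
full run takes a few minutes on one CPU.

```r
library(binpat)

fine   <- make_grid(402, 402, 0.05)  # forward grid
coarse <- make_grid(201, 201, 0.1)   # inversion grid
phantom <- generate_derenzo(fine)
truth   <- as_binary_mask(generate_derenzo(coarse))

sim <- simulate_measurement(phantom, make_detector_ring(80, 22),
                            acquisition_settings(), transducer_model(),
                            snr_db = 30, noise_seed = 1,
                            recon_grid = coarse)

out <- solve_binary(sim$A, sim$sinogram)
out$result
#> <pat_recon> method = binary, lambda = NA, 250 iterations, ||Ax-b|| = 39.99
dice(truth, as_binary_mask(out$result$image))
#> [1] 0.9683794

bp <- backproject(sim$A, sim$sinogram)
dice(truth, segment_threshold_mean(bp))
#> [1] 0.443412
```

The binary solver's Dice (0.968) measures the overlap between its
two-level output and the ground-truth mask; the backprojection comparator,
segmented by the clip-at-zero / mean-threshold protocol, trails far
behind, and Tikhonov (≈ 0.83) and L1 (≈ 0.97) reconstructions at their
best swept regularization fall in between — in that order.
`benchmark_table()` runs the whole factorial comparison and returns a tidy
table.

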