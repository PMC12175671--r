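# fourierfit

Truncated Fourier-basis fitting for real-valued fields known only on a
**masked subset of a regular grid** (1–3 spatial dimensions, optional time
axis), with smoothing, hole inpainting and extrapolation.

## Why

On a complete grid, the DFT is unitary and low-pass representations are
trivial. The moment data are *masked* — voxels missing, excluded or
unreliable, as near the brain–CSF interface in deformation (DENSE) MRI —
the restricted Fourier basis stops being orthogonal and the coefficients
must be estimated by least squares. Doing that naively is prohibitively
expensive for image-sized grids, and the resulting normal equations are
often ill-conditioned.

`fourierfit` solves

$$a_{\mathbf n} = \arg\min \sum_{\mathbf r} M(\mathbf r)\,
\Big(f(\mathbf r) - 2\,\mathrm{Re}\sum_{\mathbf n} a_{\mathbf n}
e^{j \mathbf k_{\mathbf n}\cdot\mathbf r}\Big)^2 ,
\qquad -N_i \le n_i \le N_i,$$

by

- generating the normal-equation matrix from complex **mask structure
  factors** $S_{\mathbf i} = \sum_{\mathbf r} M e^{j\mathbf k_{\mathbf i}
  \cdot\mathbf r}$, computed by separable per-axis tensor contractions
  against precomputed exponential tables;
- reducing the system to half size ($M = \prod_i (2N_i+1)$ unknowns) via
  the conjugate symmetry $a_{-\mathbf n} = a_{\mathbf n}^*$ of real fits;
- solving with **adaptive truncated-SVD regularization** (threshold 0.1,
  rank grown by 2% until the relative system residual falls below
  $3\times10^{-3}$), where the SVD is obtained from a single symmetric
  eigendecomposition thanks to the sign structure of the reduced matrix;
- reusing structure factors, matrix and factorization across **time steps
  and vector components that share one mask**, so a 20-snapshot,
  3-component deformation series pays for one factorization.

The padded Fourier period (default 10% beyond the data extent) keeps the
periodic basis from clamping extrapolation at the data boundary.

## A worked example

```r
library(fourierfit)
bm <- run_benchmark("1d")   # Ackley field, 200 points, 3 holes, N = 11
bm
#> <ff_benchmark> 1D, 200 points, N = (11)
#> <ff_deviation> in mask: max 0.003128, std 0.00161 (n=140) | holes: max 0.03502, std 0.009001 (n=60)
```

The benchmark samples an Ackley-type test function on 200 points of
$[-5,5]$, normalizes it to $[0,1]$, masks out the intervals
$[-3.5,-2.5] \cup [-0.5,0.5] \cup [2.5,3.5]$ (60 of 200 points), fits 11
harmonics and reconstructs everywhere. The numbers are reconstruction
errors in units of the normalized field range: where data existed the fit
deviates at most 0.0031 (smoothing fidelity); inside the holes — pure
interpolation — the worst error is 0.035, well below 10% of the range.

Fitting your own data:

```r
g   <- build_grid(dim(values), bounds = c(0, 100), padding_fraction = 0.1)
fit <- fit_masked_field(masked_field(values, mask), g, modes = c(4, 4, 4))
smoothed <- fit$fitted                       # reconstruction on the grid
field    <- evaluate_field(fit$coefficients, g,
                           coords = finer_axis_coords)  # off-grid
```

A command-line front end (`inst/cli/fourierfit`) exposes `fit`,
`reconstruct`, `benchmark` and `timeseries` subcommands over NIfTI and
RDS volumes.

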