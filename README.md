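# masslasso

Fast estimation of L1-regularized (lasso) linear models in the
mass-univariate setting: many response time series — typically voxel
time courses in fMRI — fitted independently against one shared design
matrix. For every voxel $j$, masslasso solves

$$\hat B_j,\ \hat B^0_j \;=\; \arg\min_{B_j,\,B^0_j}\;
\frac{1}{2n}\,\lVert Y_j - X B_j - B^0_j \mathbf 1\rVert_2^2
\;+\; \lambda\,\lVert B_j\rVert_1,$$

where $X$ is an $n \times p$ design with z-scored columns (mean zero,
$\frac1n\sum_i X_{ij}^2 = 1$, no intercept column) and $Y$ is
$n \times v$. Sparse fits of this form are the natural choice for
single-trial models, FIR models and encoding models, where $p$ is
large — often larger than $n$ — and only a few predictors are expected
to matter per voxel.

Two solvers expose the same contract:

- **`cd_solve_path()`** — cyclic coordinate descent with a precomputed
  Gram matrix shared across voxels, covariance updates (no residual
  vectors), active sets, warm starts along a decreasing λ sequence,
  fixed-capacity sparse coefficient buffers, and a deterministic
  multi-core voxel loop (`cpu_load_factor`).
- **`admm_solve_path()`** — batched ADMM that updates all coefficients
  of a block of voxels at once via matrix products, with one cached
  Cholesky factorization per design and a Woodbury
  (matrix-inversion-lemma) branch for overparameterized designs
  ($p > n$); outputs stored at single precision.

Supporting pieces: `calculate_lambda_start()` (the smallest λ with an
all-zero solution), sparse↔full coefficient conversion, a versioned
result container with delimited text export, readers for matrix files
and masked 4-D NIfTI volumes, synthetic benchmark and planted-model
generators, an independent proximal-gradient reference solver and a KKT
optimality certificate, and `estimate_memory()` for sizing buffers.

## Worked example

Simulate an overparameterized problem (300-predictor design at 60 time
points, 64 voxels — a scaled version of an encoding-model setting) and
fit a warm-started λ path:

```r
library(masslasso)

bm <- generate_benchmark(benchmark_spec("A", n = 60, p = 300, v = 64, seed = 1))
calculate_lambda_start(bm$X, bm$Y)
#> [1] 0.5376141

fit <- cd_solve_path(bm$X, bm$Y, 2^-(2:6))
fit
#> masslasso fit (cd): n = 60, p = 300, v = 64, 5 lambda value(s)
#>   lambda = 0.25       mean nonzeros/voxel = 7.67
#>   lambda = 0.125      mean nonzeros/voxel = 27.42
#>   lambda = 0.0625     mean nonzeros/voxel = 43.19
#>   lambda = 0.03125    mean nonzeros/voxel = 52.59
#>   lambda = 0.015625   mean nonzeros/voxel = 60.78
```

λ starts just below the zero-solution threshold (0.54), and the average
number of nonzero coefficients per voxel grows from ~8 toward the
saturation bound as λ decreases — on pure-noise responses the lasso
admits predictors up to roughly the number of time points. Solutions are
exactly sparse and certified: the KKT residual of any fitted voxel is a
small multiple of the stopping tolerance:

```r
B <- convert_betas_sparse_to_full(fit$per_lambda[[5]], 300)
kkt_residual(bm$X, bm$Y[, 1], B[, 1], 2^-6)
#> [1] 0.0005410259
```

The ADMM solver fits the same data with
`admm_solve_path(bm$X, bm$Y, 2^-(2:6))` and agrees with coordinate
descent in per-voxel objective to within ten times the stopping
tolerance.

A thin command-line front end wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "masslasso.R", package = "masslasso"))')" \
  fit --solver cd --design X.tsv --responses Y.tsv --lambda start,5,1 --output fit.bin
```

with further subcommands `lambda-start`, `convert`, `simulate` and
`estimate-memory`.

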