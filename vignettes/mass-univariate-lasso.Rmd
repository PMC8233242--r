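---
title: "Mass-univariate L1-regularized regression: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mass-univariate L1-regularized regression: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

In mass-univariate fMRI analysis the same linear model is fitted
independently to a large number of voxel time courses. With a design
matrix $X$ of $n$ time points by $p$ predictors and a response matrix
$Y$ of $n$ by $v$ voxels, masslasso estimates, for every voxel $j$,

$$\hat B_j, \hat B^0_j \;=\; \arg\min_{B_j,\,B^0_j}\;
\frac{1}{2n}\,\lVert Y_j - X B_j - B^0_j \mathbf 1\rVert_2^2
\;+\; \lambda\,\lVert B_j\rVert_1 .$$

The L1 penalty yields exactly sparse coefficient vectors, which is the
appropriate prior when only a small fraction of a large predictor set
(single-trial regressors, FIR basis functions, encoding-model features)
is expected to drive any one voxel. Unlike ridge regression there is no
closed form; the fit is iterative, and the package's entire design is
about amortizing that iteration over many voxels that share one design.

Two structural facts carry the whole implementation:

* The columns of $X$ must be z-scored with divisor $n$:
  $\sum_i X_{ij} = 0$ and $\frac1n\sum_i X_{ij}^2 = 1$. Then the Gram
  matrix $C = \frac1n X^\top X$ has unit diagonal, so the coordinate
  update has unit denominator, and its entries are predictor
  correlations. This is deliberately *not* the $n-1$ convention of
  `scale()`; `check_standardized()` rejects designs standardized that
  way (their second moment is $(n-1)/n$).
* Because $X$ is centered and the intercept is unpenalized, the optimal
  intercept is the response mean at every $\lambda$. It is computed once
  (`compute_intercepts()`), and $Y$ is never re-centered or copied.

All per-voxel information the solvers need is condensed into the shared
Gram matrix $C$ (computed once) and the cross-product matrix
$c = \frac1n X^\top Y$ — the "covariance updates" formulation in which
no residual vector is ever maintained.

## The coordinate descent solver

`cd_solve_path()` runs cyclic coordinate descent per voxel. The update
for coordinate $j$ is

$$\beta_j \leftarrow S\!\Big(c_{j} - \textstyle\sum_{k \ne j,\ \beta_k \ne 0}
C_{jk}\beta_k,\ \lambda\Big),$$

with $S(z,t) = \mathrm{sign}(z)\max(|z|-t,0)$. The gradient sum runs
over the currently nonzero coordinates only, so each update costs
O(active set), and the rows of $C$ for active coordinates are the hot
data. The schedule is the standard active-set scheme: one full sweep
over all $p$ coordinates, then sweeps over the active set until the
largest coordinate change in a sweep falls below `tol_value`, then one
more full sweep; if that sweep activates a new coordinate or moves any
coordinate by `tol_value` or more, the active-set phase resumes,
otherwise the voxel is converged.

Choices worth making explicit:

* **Iteration unit.** One "iteration" is one sweep (full or active-set);
  `n_iter_max` (default $10^5$) bounds total sweeps per voxel per
  $\lambda$. Counting sweeps rather than single coordinate updates makes
  the default meaningful across problem sizes.
* **Coordinate order** is fixed cyclic $1,\dots,p$ (activation order
  within active-set sweeps), with no randomization, so results are
  bit-reproducible.
* **`tol_value`** (default $10^{-3}$) is interpreted on the
  standardized-coefficient scale the solver works in.
* **Sparse buffers.** Output coefficients are stored sparsely; the
  per-voxel capacity is $\lceil \texttt{buffer\_factor} \cdot n\rceil$
  (default factor 3). If a sweep would drive the number of nonzeros past
  the capacity the whole call aborts with
  `"N_nz over maximum, larger buffer is required!"` — a hard error, not
  silent truncation. Internally each voxel still uses a dense working
  vector of length $p$: sparsity is an output format, not a working-set
  constraint, at desk-scale $p$.
* **Warm starts.** Along a decreasing $\lambda$ sequence each fit starts
  from the previous solution; the first $\lambda$ starts at zero. A
  non-decreasing sequence triggers a warning, not an error — the fits
  remain correct, only slower.
* **$\lambda = 0$** is refused when $p > n$ (the unregularized fit is
  non-unique); for $p \le n$ it is allowed and converges to OLS.
* **Parallelism.** Voxels are partitioned across
  `max(1, floor(cpu_load_factor * cores))` workers. Since voxel fits
  share only read-only precomputed matrices, results are bitwise
  identical for any worker count.

## The batched ADMM solver

`admm_solve_path()` carries the standard ADMM splitting of the lasso,
updating *all* coefficients of a block of voxels simultaneously through
matrix products:

$$B \leftarrow (C + \rho I)^{-1}(c + \rho(Z - U)), \qquad
Z \leftarrow S(B + U, \lambda/\rho), \qquad
U \leftarrow U + B - Z .$$

$Z$ is returned as the coefficient estimate; its zeros are exact. The
linear solve reuses one cached Cholesky factorization per design: of
$C + \rho I$ ($p \times p$) when $p \le n$, and, when $p > n$, of
$K = n\rho I + X X^\top$ ($n \times n$) through the matrix-inversion
lemma $(C + \rho I)^{-1} = \frac1\rho\big(I - X^\top K^{-1} X\big)$.
Voxels are processed in consecutive batches of at most `buffer_size`
(default 8192) columns; batches and batch order have no effect on
results because every column's trajectory depends only on its own
cross-products.

* **$\rho$ is fixed at 1** (exposed as an option). An adaptive $\rho$
  would invalidate the cached factorization, which is the point of the
  batched formulation; on standardized designs whose Gram spectrum is
  correlation-scaled, $\rho = 1$ is well matched.
* **Stopping rule.** A voxel is converged when the elementwise change of
  its $Z$ column is below `tol_value` *and* its primal residual
  $\max|B - Z|$ is below $10\cdot\texttt{tol\_value}$. The change
  criterion alone is not sound: from a cold start $Z$ can sit at an
  exact transient (e.g. all zeros) for an iteration while the dual is
  still accumulating, which would declare convergence far from the
  optimum — we observed objective gaps of ~0.06 in the $p > n$ regime
  with the change-only rule. Gating on primal feasibility makes
  "converged" mean "at a fixed point", where $B = Z$ holds exactly.
  Converged columns are frozen (no longer updated) rather than removed,
  preserving simple dense-block updates.
* **Warm starts** carry the full $(B, Z, U)$ triple from one $\lambda$
  to the next within a batch; warm-starting $Z$ alone discards the dual
  state that encodes the active constraints.
* **Precision.** Outputs (coefficients and intercepts) are stored at
  IEEE single precision — the storage convention of GPU-oriented
  implementations of this scheme, and a 2x memory saving at $p \times v$
  scale — by rounding doubles through float32 (`as_float32()`). All
  internal computation stays in double precision; an
  `single_precision` option iterates fully in float32-rounded
  arithmetic for fidelity experiments. On CPU there is no speed
  incentive for single precision, so correctness takes priority.
* GPU execution itself is out of scope; the contract is written so a GPU
  backend could replace the batch kernel without changing any result
  beyond stated tolerances.

Both solvers share the error message
`"Max. iter. reached, no convergence!"` when `n_iter_max` is exhausted;
for ADMM it is annotated with the batch index and $\lambda$.

## Lambda sequences

`calculate_lambda_start()` returns $\max_{j,v} |c_{jv}|$, the smallest
$\lambda$ at which the all-zero solution is optimal for every voxel
(by the KKT conditions, since all subgradient bounds $|c_{jv}| \le
\lambda$ hold at $\beta = 0$). Paths typically start there and descend
on a log2 scale; `parse_lambda_spec("start,k,step", X, Y)` builds
$\lambda_s \cdot 2^{0}, 2^{-\text{step}}, \dots$ accordingly. The
smallest $\lambda$ trades computation time against model saturation: as
the nonzero count per voxel approaches $n$, estimation slows and, for
$p > n$, destabilizes — `run_fit()` logs the fraction of voxels past
$0.9\,n$ nonzeros per $\lambda$ as a saturation guard.

## Synthetic data and what the tests can show

`generate_benchmark()` reproduces two reference configurations with
normally distributed $X$ (z-scored after sampling) and $Y$: label A,
the overparameterized case ($n = 300$, $p = 5000$, $v = 65536$,
$\lambda \in \{2^{-2},\dots,2^{-6}\}$ — an encoding model with a large
feature space), and label B, the well-defined case ($p = 200$,
$\lambda = 2^{-4}$ — a single-trial or FIR model). The test suite runs
them at reduced dimensions chosen so the full battery completes in
seconds on one core while preserving the defining shape of each regime
(A at $n = 60$, $p = 300$, $v = 64$: still $p \gg n$; B at $n = 60$,
$p = 40$, $v = 100$: still $p < n$); the full-size configurations can be
generated explicitly for profiling. `generate_planted()` adds a known
sparse truth (k nonzeros of fixed magnitude and random sign per voxel,
Gaussian noise) for recovery scoring; its defaults in the tests
($n = 200$, $p = 50$, $k = 5$, effect 1.0, noise SD 0.5) put the signal
clearly above the noise floor at $\lambda = 2^{-4}$, and the recovery
thresholds (median sign agreement $\ge 0.9$, median false positives
$< k$) were fixed once from a pilot run at the committed seed — they are
regression guards on this package's behavior, not claims about real
data. White Gaussian data has none of the temporal autocorrelation,
drift, or spatial structure of real fMRI; passing tests certify the
*optimization* (the estimates solve the stated objective), not
statistical performance on real acquisitions.

The independent reference is `ista_reference()`, plain proximal-gradient
descent with step $1/L$ ($L$ the top Gram eigenvalue), run to a much
tighter tolerance than either production solver and sharing only the
scalar soft-threshold with them. `kkt_residual()` certifies optimality
directly: at an exact solution the maximal violation of the stationarity
conditions is zero, and at a solver output it should be a small multiple
of `tol_value` (for coordinate descent, whose updates are exact
coordinate minimizations, we assert $5\cdot$`tol_value`; the ADMM
iterate's residual scales instead with $\lVert C\rVert \cdot$ distance
to the optimum, so its guarantees are stated as primal feasibility and
objective agreement with coordinate descent, both asserted at
$10\cdot$`tol_value`).

## Storage

Results live in a `masslasso_fit`: the lambda sequence, one packed
sparse coefficient set per lambda (concatenated values, 0-based
predictor indexes, per-voxel counts and offsets), the intercept row,
iteration/convergence diagnostics, and metadata including the voxel
index map when responses came from a masked NIfTI volume (linearized
with the first spatial axis fastest). `write_fit()/read_fit()` serialize
the documented hierarchical layout losslessly and verify a container
version on read; `write_fit_text()` exports one delimited file per
lambda (voxel, predictor, beta) with 1-based predictor numbering, noted
in the file header, as a nod to the Matlab-side conventions of the
original tooling. `estimate_memory()` itemizes the dominant allocations
of either solver so buffer parameters can be sized before a run.

## Known limitations

* No cross-validation or information-criterion selection of $\lambda$;
  the sequence is chosen a priori.
* No elastic-net mixing, screening rules, or randomized coordinate
  orders.
* The ADMM solver keeps dense $p \times b$ state; for very large $p$
  with small active sets, coordinate descent is the memory-sane choice.
* Readers handle delimited text, `.rds` matrices and NIfTI-1 volumes;
  writing coefficient maps back to NIfTI is left to the caller via the
  stored voxel index map.
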