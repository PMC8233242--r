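# Shared fixtures, all built in code.

# Design with centered, mutually orthogonal columns scaled so that
# (1/n) X'X = I exactly: Helmert contrasts have zero-sum orthogonal
# columns; rescale each to unit population second moment. p <= n - 1.
make_orthonormal_design <- function(n, p) {
  stopifnot(p <= n - 1)
  H <- stats::contr.helmert(n)[, seq_len(p), drop = FALSE]
  sweep(H, 2L, sqrt(colMeans(H^2)), "/")
}

# Random z-scored Gaussian design plus Gaussian responses.
rand_problem <- function(n, p, v, seed) {
  set.seed(seed)
  list(X = zscore_columns(matrix(rnorm(n * p), n, p)),
       Y = matrix(rnorm(n * v), n, v))
}

# Per-voxel objectives of a fitted path at one lambda index.
path_objectives <- function(fit, X, Y, l) {
  B <- convert_betas_sparse_to_full(fit$per_lambda[[l]], ncol(X))
  vapply(seq_len(ncol(Y)), function(v) {
    objective_value(X, Y[, v], B[, v], fit$intercepts[v], fit$lambdas[l])
  }, numeric(1))
}
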