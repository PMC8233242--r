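# Synthetic data generators and independent reference machinery: the two
# benchmark configurations (white-noise X and Y), a planted-sparse-model
# generator for recovery tests, a deliberately simple proximal-gradient
# (ISTA) solver used as a correctness oracle, and the KKT optimality
# residual. All generators are pure functions of their seed.

#' Benchmark configuration
#'
#' Describes a synthetic mass-univariate problem. Label `"A"` is the
#' overparameterized reference configuration (n = 300 time points — a
#' 10 min run at TR 2 s — p = 5000 predictors, v = 65536 voxels, lambda
#' sequence \eqn{2^{-2}, \dots, 2^{-6}}), e.g. an encoding model with a
#' large feature space. Label `"B"` is the well-defined configuration
#' (same n and v, p = 200, single lambda \eqn{2^{-4}}), e.g. a
#' single-trial or FIR model. Any dimension can be overridden (or use
#' `"custom"`); the defaults are the reference dimensions.
#'
#' @param label `"A"`, `"B"` or `"custom"`.
#' @param n,p,v optional dimension overrides.
#' @param lambda_seq optional lambda sequence override.
#' @param seed RNG seed; generation is fully determined by it.
#' @return list of class `"benchmark_spec"`.
#' @export
benchmark_spec <- function(label = c("custom", "A", "B"), n = NULL, p = NULL,
                           v = NULL, lambda_seq = NULL, seed = 1L) {
  label <- match.arg(label)
  def <- switch(label,
                A = list(n = 300L, p = 5000L, v = 65536L,
                         lambda_seq = 2^(-(2:6))),
                B = list(n = 300L, p = 200L, v = 65536L, lambda_seq = 2^-4),
                custom = list(n = 60L, p = 40L, v = 64L,
                              lambda_seq = 2^(-(2:6))))
  structure(list(label = label,
                 n = as.integer(n %||% def$n),
                 p = as.integer(p %||% def$p),
                 v = as.integer(v %||% def$v),
                 lambda_seq = as.double(lambda_seq %||% def$lambda_seq),
                 seed = as.integer(seed)),
            class = "benchmark_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate benchmark data
#'
#' Draws X and Y entries from the standard normal distribution (the
#' benchmark convention for this method), then z-scores the columns of X
#' so it satisfies the solvers' input contract. Bitwise reproducible from
#' the seed.
#'
#' @param spec a [benchmark_spec()].
#' @return list with `X` (standardized n x p), `Y` (n x v), `spec`.
#' @export
generate_benchmark <- function(spec) {
  stopifnot(inherits(spec, "benchmark_spec"))
  set.seed(spec$seed)
  X <- zscore_columns(matrix(stats::rnorm(spec$n * spec$p), spec$n, spec$p))
  Y <- matrix(stats::rnorm(spec$n * spec$v), spec$n, spec$v)
  list(X = X, Y = Y, spec = spec)
}

#' Generate a planted sparse model
#'
#' Builds responses \eqn{Y_v = X \beta_v + \varepsilon} with a known
#' sparse truth: each voxel's coefficient vector has exactly
#' `support_size` nonzeros of magnitude `effect_size` with random signs on
#' a random support, and i.i.d. normal noise with standard deviation
#' `noise_sd`. Used to score support and sign recovery.
#'
#' @param spec a [benchmark_spec()]; its `n`, `p`, `v` and `seed` are used.
#' @param support_size nonzeros per voxel (k < n).
#' @param effect_size magnitude of each true coefficient (default 1).
#' @param noise_sd noise standard deviation (default 0.5).
#' @return list with `X`, `Y`, `true_beta` (p x v), `spec`, and the model
#'   parameters.
#' @export
generate_planted <- function(spec, support_size, effect_size = 1,
                             noise_sd = 0.5) {
  stopifnot(inherits(spec, "benchmark_spec"), support_size < spec$n,
            support_size >= 1, noise_sd >= 0)
  set.seed(spec$seed)
  X <- zscore_columns(matrix(stats::rnorm(spec$n * spec$p), spec$n, spec$p))
  B <- matrix(0, spec$p, spec$v)
  for (j in seq_len(spec$v)) {
    idx <- sample.int(spec$p, support_size)
    B[idx, j] <- effect_size * sample(c(-1, 1), support_size, replace = TRUE)
  }
  Y <- X %*% B + matrix(stats::rnorm(spec$n * spec$v, sd = noise_sd),
                        spec$n, spec$v)
  list(X = X, Y = Y, true_beta = B, spec = spec,
       support_size = support_size, effect_size = effect_size,
       noise_sd = noise_sd)
}

#' Proximal-gradient (ISTA) reference solver
#'
#' Deliberately simple iteration used as an independent correctness oracle
#' for the production solvers:
#' \deqn{\beta \leftarrow S\!\left(\beta + \tfrac{1}{L}\,\tfrac{1}{n} X^\top (y - \bar y - X\beta),\ \lambda/L\right)}
#' with \eqn{L} the largest eigenvalue of the Gram matrix. No warm starts,
#' no active sets, no Gram precomputation in the iteration; the only code
#' shared with the production solvers is [soft_threshold()].
#'
#' @param X standardized design matrix.
#' @param y single response column.
#' @param lam non-negative lambda.
#' @param tol stop when the max absolute coefficient change drops below
#'   this (default `1e-8`).
#' @param n_iter_max iteration cap (default `2e5`; a warning is issued if
#'   reached).
#' @return coefficient vector of length p.
#' @export
ista_reference <- function(X, y, lam, tol = 1e-8, n_iter_max = 2e5) {
  stopifnot(tol > 0, lam >= 0)
  n <- nrow(X); p <- ncol(X)
  L <- max(eigen(crossprod(X) / n, symmetric = TRUE,
                 only.values = TRUE)$values)
  ybar <- mean(y)
  beta <- numeric(p)
  for (it in seq_len(n_iter_max)) {
    g <- crossprod(X, y - ybar - X %*% beta) / n
    bn <- soft_threshold(beta + as.vector(g) / L, lam / L)
    if (max(abs(bn - beta)) < tol) return(bn)
    beta <- bn
  }
  warning("ista_reference reached its iteration cap before the change tolerance")
  beta
}

#' KKT optimality residual for a lasso solution
#'
#' With \eqn{g = (1/n) X^\top (y - \bar y - X\beta)}, returns the maximal
#' violation of the lasso optimality conditions:
#' \eqn{|g_j - \lambda\,\mathrm{sign}(\beta_j)|} where \eqn{\beta_j \ne 0},
#' and \eqn{\max(|g_j| - \lambda, 0)} where \eqn{\beta_j = 0}. Zero at an
#' exact solution.
#'
#' @inheritParams ista_reference
#' @param beta candidate coefficient vector.
#' @return single non-negative number.
#' @export
kkt_residual <- function(X, y, beta, lam) {
  n <- nrow(X)
  g <- as.vector(crossprod(X, y - mean(y) - as.vector(X %*% beta))) / n
  nz <- beta != 0
  viol_nz <- if (any(nz)) max(abs(g[nz] - lam * sign(beta[nz]))) else 0
  viol_z <- if (any(!nz)) max(pmax(abs(g[!nz]) - lam, 0)) else 0
  max(viol_nz, viol_z)
}
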