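# Batched ADMM lasso solver: updates all coefficients of a block of voxels
# simultaneously through matrix products, with one factorization cached per
# design and a Woodbury (matrix-inversion-lemma) branch when p > n. This is
# the CPU realization of the mathematical contract of the GPU variants of
# the method; a GPU backend could be swapped in without changing results
# beyond stated tolerances.

#' Options for the batched ADMM solver
#'
#' @param n_iter_max upper bound on ADMM iterations per batch per lambda
#'   (default `1e5`).
#' @param tol_value convergence threshold on the elementwise change of the
#'   sparse iterate Z between iterations, per voxel (default `1e-3`).
#' @param buffer_size number of voxels processed simultaneously in one
#'   batch (default 8192).
#' @param rho ADMM penalty parameter (default 1). Fixed across iterations
#'   so the factorization of \eqn{C + \rho I} can be cached.
#' @param single_precision if `TRUE`, round the (B, Z, U) iterates through
#'   IEEE float32 after every iteration, mimicking a fully single-precision
#'   solver; by default iterates are double precision and only the outputs
#'   are downcast.
#' @return list of class `"admm_options"`.
#' @export
admm_options <- function(n_iter_max = 1e5, tol_value = 1e-3,
                         buffer_size = 8192, rho = 1,
                         single_precision = FALSE) {
  stopifnot(n_iter_max >= 1, tol_value > 0, buffer_size >= 1, rho > 0)
  structure(list(n_iter_max = as.integer(n_iter_max),
                 tol_value = as.double(tol_value),
                 buffer_size = as.integer(buffer_size),
                 rho = as.double(rho),
                 single_precision = isTRUE(single_precision)),
            class = "admm_options")
}

#' Cache the ADMM factorization for a design
#'
#' The ADMM quadratic block solves \eqn{(C + \rho I) B = R} every
#' iteration, with \eqn{C = (1/n) X^\top X}. For p <= n the p x p matrix
#' \eqn{C + \rho I} is Cholesky-factorized directly. For p > n
#' (overparameterized) the matrix-inversion lemma
#' \deqn{(C + \rho I)^{-1} = \frac{1}{\rho}\left(I - X^\top (n\rho I + X X^\top)^{-1} X\right)}
#' reduces the work to an n x n factorization of
#' \eqn{K = n\rho I + X X^\top}. Either factor is computed once and reused
#' across all batches, iterations and lambda values.
#'
#' @param X standardized design matrix.
#' @param rho positive ADMM penalty parameter.
#' @return object of class `"admm_factorization"` with fields `branch`
#'   (`"underparameterized"` or `"overparameterized"`), `factor` (upper
#'   Cholesky factor), `rho`, and the design dimensions.
#' @export
admm_prepare <- function(X, rho = 1) {
  assert_standardized(X)
  stopifnot(rho > 0)
  n <- nrow(X); p <- ncol(X)
  if (p <= n) {
    M <- compute_gram(X) + diag(rho, p)
    fac <- tryCatch(chol(M), error = function(e)
      stop("factorization of C + rho*I failed (should be impossible for rho > 0; check the input for corruption): ",
           conditionMessage(e), call. = FALSE))
    structure(list(branch = "underparameterized", factor = fac, rho = rho,
                   X = NULL, n = n, p = p),
              class = "admm_factorization")
  } else {
    K <- diag(n * rho, n) + tcrossprod(X)
    fac <- tryCatch(chol(K), error = function(e)
      stop("factorization of n*rho*I + X*X' failed (should be impossible for rho > 0; check the input for corruption): ",
           conditionMessage(e), call. = FALSE))
    structure(list(branch = "overparameterized", factor = fac, rho = rho,
                   X = X, n = n, p = p),
              class = "admm_factorization")
  }
}

# Internal: apply (C + rho*I)^{-1} to a p x b block using the cached factor.
admm_apply_inverse <- function(fac, B) {
  if (fac$branch == "underparameterized") {
    backsolve(fac$factor, backsolve(fac$factor, B, transpose = TRUE))
  } else {
    W <- backsolve(fac$factor,
                   backsolve(fac$factor, fac$X %*% B, transpose = TRUE))
    (B - crossprod(fac$X, W)) / fac$rho
  }
}

#' ADMM on one batch of voxels
#'
#' Iterates, for all voxels of the batch at once,
#' \deqn{B \leftarrow (C + \rho I)^{-1} (c + \rho (Z - U)), \quad
#'       Z \leftarrow S(B + U, \lambda/\rho), \quad
#'       U \leftarrow U + B - Z,}
#' using the cached factorization (Woodbury path when overparameterized).
#' A voxel is converged when the max elementwise change of its Z column
#' drops below `tol_value` and its primal residual `max |B - Z|` drops
#' below `10 * tol_value`; converged columns are frozen. Z is returned as
#' the coefficient estimate (its zeros are exact, produced by
#' soft-thresholding).
#'
#' @param fac factorization from [admm_prepare()].
#' @param c_batch p x b cross-product block for the batch.
#' @param lam non-negative lambda.
#' @param init optional warm-start state (a previous return value: fields
#'   `B`, `Z`, `U`).
#' @param opts [admm_options()].
#' @return list with `B`, `Z`, `U` (p x b), `iterations_used`,
#'   `converged_mask`, and `voxel_iterations` (iteration at which each
#'   voxel's column converged).
#' @export
admm_solve_batch <- function(fac, c_batch, lam, init = NULL,
                             opts = admm_options()) {
  c_batch <- as.matrix(c_batch)
  p <- nrow(c_batch); b <- ncol(c_batch)
  stopifnot(p == fac$p, lam >= 0)
  if (b > opts$buffer_size) {
    stop(sprintf("batch of %d voxels exceeds buffer_size = %d", b,
                 opts$buffer_size))
  }
  if (is.null(init)) {
    B <- Z <- U <- matrix(0, p, b)
  } else {
    stopifnot(all(dim(init$Z) == c(p, b)))
    B <- init$B; Z <- init$Z; U <- init$U
  }
  rho <- fac$rho
  act <- seq_len(b)
  converged_mask <- logical(b)
  voxel_iterations <- integer(b)
  iter <- 0L
  while (length(act)) {
    if (iter >= opts$n_iter_max) stop(MSG_MAXITER, call. = FALSE)
    iter <- iter + 1L
    rhs <- c_batch[, act, drop = FALSE] +
      rho * (Z[, act, drop = FALSE] - U[, act, drop = FALSE])
    Bn <- admm_apply_inverse(fac, rhs)
    Tn <- Bn + U[, act, drop = FALSE]
    Zn <- soft_threshold(Tn, lam / rho)
    Un <- Tn - Zn
    if (opts$single_precision) {
      Bn <- as_float32(Bn); Zn <- as_float32(Zn); Un <- as_float32(Un)
    }
    ch <- apply(abs(Zn - Z[, act, drop = FALSE]), 2L, max)
    primal <- apply(abs(Bn - Zn), 2L, max)
    B[, act] <- Bn; Z[, act] <- Zn; U[, act] <- Un
    # The change criterion alone can stall-converge from a cold start (Z can
    # sit at an exact transient for an iteration, e.g. all-zero while the
    # dual still accumulates); requiring primal feasibility as well makes
    # "converged" mean "at a fixed point", where B = Z holds exactly.
    done <- ch < opts$tol_value & primal < 10 * opts$tol_value
    if (any(done)) {
      converged_mask[act[done]] <- TRUE
      voxel_iterations[act[done]] <- iter
      act <- act[!done]
    }
  }
  list(B = B, Z = Z, U = U, iterations_used = iter,
       converged_mask = converged_mask, voxel_iterations = voxel_iterations)
}

#' Batched ADMM along a lambda path, all voxels
#'
#' Splits the voxels into consecutive batches of at most
#' `opts$buffer_size`; within each batch, lambda values are visited in
#' sequence order with the full (B, Z, U) triple carried over as the warm
#' start. Coefficients and intercepts are stored at single precision (the
#' storage convention of the GPU-oriented variants); all internal
#' computation is double precision unless `opts$single_precision`.
#'
#' @inheritParams cd_solve_path
#' @param opts [admm_options()].
#' @return [fit_result] object (solver `"admmbatch"`).
#' @export
admm_solve_path <- function(X, Y, lambda_seq, opts = admm_options()) {
  Y <- as.matrix(Y)
  assert_standardized(X)
  assert_responses(X, Y)
  lambda_seq <- validate_lambda_seq(lambda_seq)
  n <- nrow(X); p <- ncol(X); v <- ncol(Y); L <- length(lambda_seq)
  if (any(lambda_seq == 0) && p > n) {
    stop("lambda = 0 is not allowed for overparameterized designs (p > n): the unregularized fit is non-unique; use a positive lambda")
  }
  fac <- admm_prepare(X, opts$rho)
  cp <- compute_crossproducts(X, Y)
  b0 <- compute_intercepts(Y)

  starts <- seq.int(1L, v, by = opts$buffer_size)
  iters <- matrix(0L, L, v)
  dense <- vector("list", L)
  for (l in seq_len(L)) dense[[l]] <- matrix(0, p, v)

  for (bi in seq_along(starts)) {
    cols <- starts[bi]:min(starts[bi] + opts$buffer_size - 1L, v)
    state <- NULL
    for (l in seq_len(L)) {
      state <- tryCatch(
        admm_solve_batch(fac, cp[, cols, drop = FALSE], lambda_seq[l],
                         init = state, opts = opts),
        error = function(e) stop(sprintf("%s (batch %d, lambda %g)",
                                         conditionMessage(e), bi,
                                         lambda_seq[l]), call. = FALSE))
      dense[[l]][, cols] <- as_float32(state$Z)
      iters[l, cols] <- state$voxel_iterations
    }
  }

  per_lambda <- lapply(dense, convert_betas_full_to_sparse)
  new_fit_result(lambdas = lambda_seq, per_lambda = per_lambda,
                 intercepts = as_float32(b0),
                 diagnostics = list(iterations = iters,
                                    converged = matrix(TRUE, L, v)),
                 meta = list(n = n, p = p, v = v, solver = "admmbatch",
                             options = unclass(opts),
                             version = as.character(utils::packageVersion("masslasso"))))
}
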