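# Coordinate-descent lasso (CPU path): per-voxel cyclic descent on the
# precomputed Gram matrix, with active sets, warm starts along the lambda
# sequence, fixed-capacity sparse output buffers and a deterministic
# parallel-execution contract.

#' Options for the coordinate descent solver
#'
#' @param n_iter_max upper bound on coordinate sweeps per voxel per lambda
#'   (default `1e5`). One iteration = one sweep, full or active-set.
#' @param tol_value convergence threshold: the solver stops when
#'   \eqn{\max_j |\beta_j^{new} - \beta_j^{old}|} within a sweep drops below
#'   this value (default `1e-3`), on the standardized-coefficient scale.
#' @param buffer_factor the per-voxel sparse output buffer holds
#'   `ceiling(buffer_factor * n)` coefficients (default 3). In well-defined
#'   settings (p <= n) a factor of 1 suffices; overparameterized fits may
#'   need more.
#' @param cpu_load_factor fraction of CPU cores to engage, in \[0, 1\]
#'   (default 1 = all cores; 0 = a single core; 0.99 = all but one on a
#'   16-core machine).
#' @return list of class `"cd_options"`.
#' @export
cd_options <- function(n_iter_max = 1e5, tol_value = 1e-3,
                       buffer_factor = 3, cpu_load_factor = 1) {
  stopifnot(n_iter_max >= 1, tol_value > 0, buffer_factor > 0,
            cpu_load_factor >= 0, cpu_load_factor <= 1)
  structure(list(n_iter_max = as.integer(n_iter_max),
                 tol_value = as.double(tol_value),
                 buffer_factor = as.double(buffer_factor),
                 cpu_load_factor = as.double(cpu_load_factor)),
            class = "cd_options")
}

#' Number of workers for a given CPU load factor
#'
#' `max(1, floor(cpu_load_factor * available_cores))`. Voxel fits are
#' independent, so results do not depend on the worker count.
#'
#' @param cpu_load_factor real in \[0, 1\].
#' @param available_cores positive integer; defaults to
#'   [parallel::detectCores()].
#' @return positive integer.
#' @export
#' @examples
#' resolve_worker_count(0.99, 16)  # 15
resolve_worker_count <- function(cpu_load_factor,
                                 available_cores = parallel::detectCores()) {
  stopifnot(cpu_load_factor >= 0, cpu_load_factor <= 1, available_cores >= 1)
  max(1L, as.integer(floor(cpu_load_factor * available_cores)))
}

#' Coordinate descent for a single voxel
#'
#' Solves one lasso problem in Gram form: cyclically updates
#' \eqn{\beta_j \leftarrow S(c_j - \sum_{k \ne j} C_{jk}\beta_k, \lambda)}
#' (unit denominator because the standardized design gives \eqn{C_{jj}=1}),
#' with gradients accumulated over the currently-nonzero coordinates only.
#' Schedule: one full sweep, then active-set sweeps until stable, then a
#' full sweep to admit newcomers, repeated until a full sweep neither
#' activates a coordinate nor moves any coordinate by `tol_value`.
#'
#' @param C Gram matrix from [compute_gram()] (unit diagonal).
#' @param c_v cross-product vector of length p for this voxel.
#' @param lam non-negative lambda.
#' @param init optional dense warm-start vector (default all zero).
#' @param opts [cd_options()].
#' @param capacity optional cap on simultaneously nonzero coefficients;
#'   exceeding it aborts with the buffer-overflow error. Default: no cap.
#' @return list with `beta` (dense length-p vector), `active` (indices of
#'   nonzeros, 1-based), `iterations` (sweeps used), `converged`.
#' @export
cd_solve_voxel <- function(C, c_v, lam, init = NULL, opts = cd_options(),
                           capacity = NULL) {
  p <- ncol(C)
  stopifnot(length(c_v) == p, lam >= 0)
  if (is.null(init)) init <- numeric(p)
  stopifnot(length(init) == p)
  if (is.null(capacity)) capacity <- p
  st <- cd_solve_voxel_cpp(C, as.double(c_v), lam, as.double(init),
                           opts$n_iter_max, opts$tol_value,
                           as.integer(capacity))
  if (st$overflow) stop(MSG_BUFFER, call. = FALSE)
  if (!st$converged) stop(MSG_MAXITER, call. = FALSE)
  list(beta = st$beta, active = which(st$beta != 0),
       iterations = st$iterations, converged = st$converged)
}

#' Coordinate descent along a lambda path, all voxels
#'
#' Fits every voxel at every lambda in sequence order, warm-starting each
#' fit from the previous lambda's solution (the first lambda starts at
#' zero). The Gram matrix and cross-products are computed once; voxel fits
#' are distributed over workers and are bitwise independent of the worker
#' count.
#'
#' @param X standardized design matrix (n x p); validated with
#'   [check_standardized()].
#' @param Y response matrix (n x v).
#' @param lambda_seq decreasing lambda sequence (a non-decreasing one
#'   triggers a warning, not an error).
#' @param opts [cd_options()].
#' @param workers optional worker count override; default
#'   [resolve_worker_count()] applied to `opts$cpu_load_factor`.
#' @return [fit_result] object (solver `"cd"`).
#' @export
cd_solve_path <- function(X, Y, lambda_seq, opts = cd_options(),
                          workers = NULL) {
  Y <- as.matrix(Y)
  assert_standardized(X)
  assert_responses(X, Y)
  lambda_seq <- validate_lambda_seq(lambda_seq)
  n <- nrow(X); p <- ncol(X); v <- ncol(Y); L <- length(lambda_seq)
  if (any(lambda_seq == 0) && p > n) {
    stop("lambda = 0 is not allowed for overparameterized designs (p > n): the unregularized fit is non-unique; use a positive lambda")
  }
  capacity <- as.integer(ceiling(opts$buffer_factor * n))
  if (is.null(workers)) workers <- resolve_worker_count(opts$cpu_load_factor)

  C <- compute_gram(X)
  cp <- compute_crossproducts(X, Y)
  b0 <- compute_intercepts(Y)

  fit_chunk <- function(voxels) {
    betas <- array(0, dim = c(p, length(voxels), L))
    iters <- matrix(0L, L, length(voxels))
    for (i in seq_along(voxels)) {
      beta <- numeric(p)
      for (l in seq_len(L)) {
        st <- cd_solve_voxel_cpp(C, cp[, voxels[i]], lambda_seq[l], beta,
                                 opts$n_iter_max, opts$tol_value, capacity)
        if (st$overflow) stop(MSG_BUFFER, call. = FALSE)
        if (!st$converged) stop(MSG_MAXITER, call. = FALSE)
        beta <- st$beta
        betas[, i, l] <- beta
        iters[l, i] <- st$iterations
      }
    }
    list(betas = betas, iters = iters)
  }

  chunks <- parallel::splitIndices(v, min(workers, v))
  if (workers > 1L && .Platform$OS.type == "unix") {
    res <- parallel::mclapply(chunks, fit_chunk, mc.cores = workers,
                              mc.preschedule = TRUE)
    for (r in res) {
      if (inherits(r, "try-error")) stop(conditionMessage(attr(r, "condition")),
                                         call. = FALSE)
    }
  } else {
    res <- lapply(chunks, fit_chunk)
  }

  iters <- matrix(0L, L, v)
  per_lambda <- vector("list", L)
  dense <- matrix(0, p, v)
  for (l in seq_len(L)) {
    for (k in seq_along(chunks)) {
      dense[, chunks[[k]]] <- res[[k]]$betas[, , l]
      iters[l, chunks[[k]]] <- res[[k]]$iters[l, ]
    }
    per_lambda[[l]] <- convert_betas_full_to_sparse(dense)
  }

  new_fit_result(lambdas = lambda_seq, per_lambda = per_lambda,
                 intercepts = b0,
                 diagnostics = list(iterations = iters,
                                    converged = matrix(TRUE, L, v)),
                 meta = list(n = n, p = p, v = v, solver = "cd",
                             options = unclass(opts),
                             version = as.character(utils::packageVersion("masslasso"))))
}
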