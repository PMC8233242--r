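# Shared mathematical substrate: standardization, Gram and cross-product
# precomputation, lambda_start, soft-thresholding, objective evaluation,
# intercepts. Both solvers work exclusively on these precomputed pieces.

#' Z-score the columns of a design matrix
#'
#' Centers every column to mean zero and scales it to unit *population*
#' second moment, i.e. \eqn{\sum_i X_{ij} = 0} and
#' \eqn{(1/n)\sum_i X_{ij}^2 = 1}. Note the divisor is `n`, not the
#' `n - 1` of [scale()]: with this convention the Gram matrix
#' \eqn{(1/n) X^\top X} has unit diagonal, which both solvers rely on.
#'
#' @param raw_design numeric matrix (n rows = time points, p columns =
#'   predictors), n >= 2, no constant column, all entries finite.
#' @return the standardized matrix, with the per-column centers and scales
#'   attached as attributes `"scaled:center"` and `"scaled:scale"` so that
#'   coefficients can be mapped back to the original units.
#' @seealso [check_standardized()]
#' @export
#' @examples
#' X <- zscore_columns(matrix(rnorm(40), 10, 4))
#' colSums(X)            # ~0
#' colMeans(X^2)         # ~1
zscore_columns <- function(raw_design) {
  X <- as.matrix(raw_design)
  storage.mode(X) <- "double"
  if (nrow(X) < 2L) stop("design matrix must have at least 2 rows")
  if (!all(is.finite(X))) stop("design matrix contains non-finite entries")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr, "-")
  scl <- sqrt(colMeans(Xc^2))
  bad <- which(scl == 0)
  if (length(bad)) {
    stop(sprintf("column %d of the design matrix is constant and cannot be z-scored",
                 bad[1L]))
  }
  out <- sweep(Xc, 2L, scl, "/")
  attr(out, "scaled:center") <- ctr
  attr(out, "scaled:scale") <- scl
  out
}

#' Check that a design matrix is z-scored
#'
#' Reports, per column, whether the centering condition
#' \eqn{\sum_i X_{ij} = 0} and the unit-second-moment condition
#' \eqn{(1/n)\sum_i X_{ij}^2 = 1} hold. The solver entry points call this
#' and refuse non-conforming input; a design standardized with divisor
#' `n - 1` fails the moment check (its second moment is `(n-1)/n`).
#'
#' @param X numeric matrix.
#' @param center_tol tolerance on `|colSum| / n` (default `1e-8`).
#' @param moment_tol tolerance on `|second moment - 1|` (default `1e-6`).
#' @return data frame with columns `column`, `mean`, `second_moment`,
#'   `centered`, `unit_moment`, `pass`; attribute `"ok"` is `TRUE` iff all
#'   columns pass.
#' @export
check_standardized <- function(X, center_tol = 1e-8, moment_tol = 1e-6) {
  X <- as.matrix(X)
  n <- nrow(X)
  mu <- colMeans(X)
  m2 <- colMeans(X^2)
  centered <- abs(mu) <= center_tol
  unit_moment <- abs(m2 - 1) <= moment_tol
  rep <- data.frame(column = seq_len(ncol(X)), mean = mu, second_moment = m2,
                    centered = centered, unit_moment = unit_moment,
                    pass = centered & unit_moment, row.names = NULL)
  attr(rep, "ok") <- all(rep$pass)
  rep
}

# Internal: stop with a pointer at the first failing column.
assert_standardized <- function(X, what = "design matrix") {
  rep <- check_standardized(X)
  if (!attr(rep, "ok")) {
    bad <- rep$column[!rep$pass][1L]
    stop(sprintf(paste0("%s is not z-scored: column %d has mean %.3g and ",
                        "second moment %.6g (need mean 0, (1/n)*sum(x^2) = 1; ",
                        "see zscore_columns)"),
                 what, bad, rep$mean[bad], rep$second_moment[bad]))
  }
  invisible(rep)
}

# Internal: common response-matrix validation.
assert_responses <- function(X, Y) {
  if (nrow(Y) != nrow(X)) {
    stop(sprintf("Y has %d rows but X has %d; time axes must match",
                 nrow(Y), nrow(X)))
  }
  if (!all(is.finite(Y))) stop("Y contains non-finite entries")
  invisible(TRUE)
}

#' Gram (predictor covariance) matrix of a standardized design
#'
#' Computes \eqn{C = (1/n) X^\top X} once; the same matrix is shared
#' read-only by every voxel fit, which is what makes precomputation pay off
#' in the mass-univariate setting. With z-scored columns the entries are
#' predictor correlations and the diagonal is 1.
#'
#' @param X standardized design matrix (see [zscore_columns()]).
#' @param max_bytes optional memory budget in bytes; if the p x p Gram
#'   matrix would exceed it, an error citing [estimate_memory()] is raised.
#' @return symmetric p x p matrix.
#' @export
compute_gram <- function(X, max_bytes = Inf) {
  assert_standardized(X)
  p <- ncol(X)
  if (8 * as.double(p)^2 > max_bytes) {
    stop(sprintf("Gram matrix needs %.0f bytes, over the budget of %.0f; see estimate_memory()",
                 8 * as.double(p)^2, max_bytes))
  }
  crossprod(X) / nrow(X)
}

#' Predictor-response cross-products
#'
#' Computes the p x v matrix with entries
#' \eqn{c_{jv} = (1/n)\langle X_j, Y_v \rangle}. Together with the Gram
#' matrix these are the only statistics the coordinate updates need
#' ("covariance updates": no residual vector is ever formed). Because X's
#' columns are centered, the result is invariant to adding a constant to
#' any column of Y.
#'
#' @param X standardized design matrix.
#' @param Y numeric response matrix with the same number of rows.
#' @return p x v numeric matrix.
#' @export
compute_crossproducts <- function(X, Y) {
  Y <- as.matrix(Y)
  assert_responses(X, Y)
  crossprod(X, Y) / nrow(X)
}

#' Unregularized intercepts
#'
#' Returns the mean of every response column. Because the design columns
#' are centered and the intercept is unpenalized, this is the exact
#' intercept of the penalized optimum at every lambda, so it is computed
#' once, independently of the solvers.
#'
#' @param Y numeric response matrix (n x v).
#' @return numeric vector of length v.
#' @export
compute_intercepts <- function(Y) {
  unname(colMeans(as.matrix(Y)))
}

#' Smallest lambda with an all-zero solution
#'
#' Returns \eqn{\max_{j,v} |c_{jv}|} with `c` from
#' [compute_crossproducts()]. For any lambda at or above this value the
#' all-zero coefficient vector satisfies the lasso optimality conditions
#' for every voxel, so the first element of a lambda sequence is typically
#' set at (or just below) this threshold.
#'
#' @param X standardized design matrix.
#' @param Y response matrix.
#' @return single non-negative number.
#' @seealso [lambda_start_per_voxel()] for the per-voxel thresholds.
#' @export
calculate_lambda_start <- function(X, Y) {
  max(abs(compute_crossproducts(X, Y)))
}

#' Per-voxel zero-solution thresholds
#'
#' @inheritParams calculate_lambda_start
#' @return numeric vector of length v: \eqn{\max_j |c_{jv}|} per voxel.
#' @export
lambda_start_per_voxel <- function(X, Y) {
  apply(abs(compute_crossproducts(X, Y)), 2L, max)
}

#' Soft-thresholding operator
#'
#' \eqn{S(z, t) = \mathrm{sign}(z)\,\max(|z| - t, 0)}, the proximal
#' operator of the L1 norm and the per-coordinate minimizer of the
#' penalized objective. Vectorized over `z`.
#'
#' @param z numeric vector or matrix.
#' @param t non-negative threshold.
#' @return object of the same shape as `z`.
#' @export
#' @examples
#' soft_threshold(c(0.5, -0.5, 0.1), 0.2)
soft_threshold <- function(z, t) {
  if (t < 0) stop("threshold must be non-negative")
  sign(z) * pmax(abs(z) - t, 0)
}

#' Lasso objective for one voxel
#'
#' Evaluates
#' \eqn{\frac{1}{2n}\|y - X\beta - b_0\mathbf{1}\|_2^2 + \lambda\|\beta\|_1}.
#'
#' @param X design matrix (n x p).
#' @param y response vector of length n.
#' @param beta coefficient vector of length p.
#' @param b0 intercept.
#' @param lam non-negative regularization parameter.
#' @return single number.
#' @export
objective_value <- function(X, y, beta, b0, lam) {
  n <- nrow(X)
  r <- y - as.vector(X %*% beta) - b0
  sum(r^2) / (2 * n) + lam * sum(abs(beta))
}

#' Validate a lambda sequence
#'
#' Checks finiteness and non-negativity; a non-(strictly-)decreasing
#' sequence triggers a warning (warm starts along the path assume
#' decreasing order but the fit is still correct in any order).
#'
#' @param lambda_seq numeric vector.
#' @return the sequence, invisibly usable.
#' @export
validate_lambda_seq <- function(lambda_seq) {
  lambda_seq <- as.double(lambda_seq)
  if (!length(lambda_seq)) stop("lambda sequence is empty")
  if (!all(is.finite(lambda_seq)) || any(lambda_seq < 0)) {
    stop("lambda values must be finite and non-negative")
  }
  if (length(lambda_seq) > 1L && any(diff(lambda_seq) >= 0)) {
    warning("lambda sequence is not strictly decreasing; warm starts along the path assume decreasing order")
  }
  lambda_seq
}
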