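# FitResult container, sparse <-> full coefficient conversion, on-disk
# formats, memory estimation.
#
# Container layout (one hierarchical list, serialized losslessly):
#   container_version                 format version string
#   lambdas                           numeric vector
#   per_lambda/<l>/{values,indexes,counts,offsets}   sparse coefficients,
#                                     indexes 0-based (see below)
#   intercepts                        length-v vector
#   diagnostics/{iterations,converged}  L x v matrices
#   meta/{n,p,v,solver,options,version,...}
# The text export writes one delimited file per lambda with columns
# voxel, predictor, beta; there, predictor numbering is 1-based.

FIT_CONTAINER_VERSION <- "1.0"

#' Construct a fit result
#'
#' Bundles a fitted lambda path: one sparse coefficient set per lambda,
#' the intercept row, per-voxel/per-lambda convergence diagnostics and
#' provenance metadata. Normally produced by [cd_solve_path()] or
#' [admm_solve_path()].
#'
#' @param lambdas lambda sequence used.
#' @param per_lambda list of sparse beta sets (one per lambda), see
#'   [convert_betas_full_to_sparse()].
#' @param intercepts numeric vector of length v.
#' @param diagnostics list with `iterations` and `converged`, both
#'   length(lambdas) x v.
#' @param meta list with at least `n`, `p`, `v`, `solver`, `options`,
#'   `version`.
#' @return object of class `"masslasso_fit"`.
#' @export
new_fit_result <- function(lambdas, per_lambda, intercepts, diagnostics,
                           meta) {
  stopifnot(length(per_lambda) == length(lambdas),
            all(vapply(per_lambda, function(s)
              length(s$counts) == meta$v, logical(1))),
            length(intercepts) == meta$v)
  structure(list(lambdas = as.double(lambdas), per_lambda = per_lambda,
                 intercepts = as.double(intercepts),
                 diagnostics = diagnostics, meta = meta),
            class = "masslasso_fit")
}

#' @export
print.masslasso_fit <- function(x, ...) {
  cat(sprintf("masslasso fit (%s): n = %d, p = %d, v = %d, %d lambda value(s)\n",
              x$meta$solver, x$meta$n, x$meta$p, x$meta$v, length(x$lambdas)))
  nnz <- vapply(x$per_lambda, function(s) sum(s$counts), numeric(1))
  for (l in seq_along(x$lambdas)) {
    cat(sprintf("  lambda = %-10.6g mean nonzeros/voxel = %.2f\n",
                x$lambdas[l], nnz[l] / x$meta$v))
  }
  invisible(x)
}

#' Sparse coefficient storage from a dense matrix
#'
#' Extracts the exact nonzeros of a dense p x v coefficient matrix into
#' packed sparse form: concatenated `values`, matching 0-based predictor
#' `indexes`, per-voxel `counts` (N_nz) and per-voxel start `offsets`
#' (0-based into `values`). No thresholding is applied — both solvers
#' produce exact zeros by soft-thresholding, so sparsity is structural.
#'
#' @param dense p x v numeric matrix.
#' @return list of class `"sparse_beta_set"`.
#' @export
convert_betas_full_to_sparse <- function(dense) {
  dense <- as.matrix(dense)
  p <- nrow(dense); v <- ncol(dense)
  nz <- which(dense != 0)  # column-major: per-voxel indexes come out increasing
  counts <- as.integer(colSums(dense != 0))
  structure(list(values = as.double(dense[nz]),
                 indexes = as.integer((nz - 1L) %% p),
                 counts = counts,
                 offsets = as.integer(utils::head(cumsum(c(0L, counts)), v)),
                 p = as.integer(p)),
            class = "sparse_beta_set")
}

#' Dense coefficient matrix from sparse storage
#'
#' Inverse of [convert_betas_full_to_sparse()]: scatters the stored
#' values into a dense p x v matrix of zeros.
#'
#' @param sparse a `sparse_beta_set` (fields `values`, `indexes` 0-based,
#'   `counts`, `offsets`).
#' @param p number of predictors (rows of the result).
#' @return dense p x v numeric matrix.
#' @export
#' @examples
#' s <- convert_betas_full_to_sparse(diag(3))
#' convert_betas_sparse_to_full(s, 3)
convert_betas_sparse_to_full <- function(sparse, p) {
  v <- length(sparse$counts)
  stopifnot(sum(sparse$counts) == length(sparse$values),
            length(sparse$values) == length(sparse$indexes))
  if (length(sparse$indexes) && (min(sparse$indexes) < 0 ||
                                 max(sparse$indexes) >= p)) {
    stop(sprintf("predictor index out of range: indexes must lie in [0, %d)", p))
  }
  col <- rep.int(seq_len(v), sparse$counts)
  if (anyDuplicated(col * as.double(p) + sparse$indexes)) {
    stop("duplicate predictor index within a voxel")
  }
  out <- matrix(0, p, v)
  out[cbind(sparse$indexes + 1L, col)] <- sparse$values
  out
}

#' Write a fit result to disk
#'
#' Serializes the full hierarchical container (layout documented in the
#' package sources) losslessly: double- and single-precision values round
#' trip bitwise. Use [write_fit_text()] for the plain-text export.
#'
#' @param result a `masslasso_fit`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(result, path) {
  stopifnot(inherits(result, "masslasso_fit"))
  obj <- unclass(result)
  obj$container_version <- FIT_CONTAINER_VERSION
  saveRDS(obj, path)
  invisible(path)
}

#' Read a fit result from disk
#'
#' @param path file written by [write_fit()].
#' @return the `masslasso_fit`.
#' @export
read_fit <- function(path) {
  obj <- readRDS(path)
  ver <- obj$container_version
  if (is.null(ver) || !identical(ver, FIT_CONTAINER_VERSION)) {
    stop(sprintf("fit container version mismatch: file has %s, this package reads %s",
                 if (is.null(ver)) "<none>" else ver, FIT_CONTAINER_VERSION))
  }
  obj$container_version <- NULL
  structure(obj, class = "masslasso_fit")
}

#' Export a fit result as delimited text
#'
#' Writes one tab-separated file per lambda (`beta_lambda_<i>.tsv`) with
#' columns `voxel`, `predictor`, `beta`, one row per stored nonzero.
#' Predictor numbering in the text export is 1-based (a header comment
#' says so); the binary container keeps 0-based indexes.
#'
#' @param result a `masslasso_fit`.
#' @param dir output directory (created if missing).
#' @return character vector of file paths, invisibly.
#' @export
write_fit_text <- function(result, dir) {
  stopifnot(inherits(result, "masslasso_fit"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(result$lambdas))
  for (l in seq_along(result$lambdas)) {
    s <- result$per_lambda[[l]]
    df <- data.frame(voxel = rep.int(seq_along(s$counts), s$counts),
                     predictor = s$indexes + 1L,
                     beta = s$values)
    paths[l] <- file.path(dir, sprintf("beta_lambda_%d.tsv", l))
    con <- file(paths[l], "w")
    writeLines(sprintf("# lambda = %.17g; predictor numbering is 1-based",
                       result$lambdas[l]), con)
    close(con)
    data.table::fwrite(df, paths[l], sep = "\t", append = TRUE,
                       col.names = TRUE)
  }
  invisible(paths)
}

#' Estimate solver memory requirements
#'
#' Itemized estimate of the dominant allocations, in bytes. For the
#' coordinate descent solver: the p x p Gram matrix, one dense working
#' beta vector per worker, and the fixed-capacity sparse output buffers
#' (`ceiling(buffer_factor * n)` value/index pairs per voxel). For the
#' ADMM solver: the cached factorization (`min(p, n)^2` doubles), the
#' (B, Z, U) triple for one batch, and the batch's cross-product block.
#'
#' @param n,p,v problem dimensions.
#' @param buffer_factor CD output buffer factor (default 3).
#' @param buffer_size ADMM batch size (default 8192).
#' @param solver `"cd"` or `"admm"`.
#' @param workers CD worker count (default 1).
#' @return list with `items` (named numeric, bytes) and `total`.
#' @export
#' @examples
#' estimate_memory(300, 5000, 65536, solver = "admm")$items
estimate_memory <- function(n, p, v, buffer_factor = 3, buffer_size = 8192,
                            solver = c("cd", "admm"), workers = 1) {
  solver <- match.arg(solver)
  n <- as.double(n); p <- as.double(p); v <- as.double(v)
  idx_bytes <- 4  # 32-bit integer indexes
  items <- if (solver == "cd") {
    c(gram = p^2 * 8,
      working_beta = workers * p * 8,
      output_buffers = ceiling(buffer_factor * n) * v * (8 + idx_bytes))
  } else {
    c(factorization = min(p, n)^2 * 8,
      batch_state = 3 * p * buffer_size * 8,
      crossproduct_block = p * buffer_size * 8)
  }
  list(items = items, total = sum(items))
}
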