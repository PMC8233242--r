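# Standardization, precomputed statistics, lambda_start, soft threshold,
# objective.

test_that("zscore_columns produces mean 0 and population second moment 1", {
  z <- zscore_columns(matrix(c(1, 2, 3), 3, 1))
  expect_equal(sum(z), 0, tolerance = 1e-12)
  expect_equal(mean(z^2), 1, tolerance = 1e-12)

  # already-standardized input is returned unchanged
  z2 <- zscore_columns(z)
  expect_equal(as.vector(z2), as.vector(z), tolerance = 1e-12)

  # random matrix: invariants hold and scales match a two-pass sd oracle
  set.seed(1)
  raw <- matrix(rnorm(40), 10, 4)
  z <- zscore_columns(raw)
  expect_true(attr(check_standardized(z), "ok"))
  twopass <- apply(raw, 2, function(col) {
    m <- sum(col) / length(col)
    sqrt(sum((col - m)^2) / length(col))
  })
  expect_equal(attr(z, "scaled:scale"), twopass, tolerance = 1e-12)
  expect_equal(attr(z, "scaled:center"), colMeans(raw), tolerance = 1e-12)
})

test_that("zscore_columns rejects constant columns and non-finite entries", {
  bad <- cbind(rnorm(8), rep(2, 8))
  expect_error(zscore_columns(bad), "column 2.*constant")
  nf <- matrix(rnorm(8), 4, 2)
  nf[2, 1] <- NA
  expect_error(zscore_columns(nf), "non-finite")
})

test_that("check_standardized flags non-conforming columns", {
  set.seed(2)
  z <- zscore_columns(matrix(rnorm(60), 10, 6))
  expect_true(attr(check_standardized(z), "ok"))

  withc <- cbind(z, 2)  # constant column
  rep <- check_standardized(withc)
  expect_false(rep$centered[7])
  expect_false(rep$unit_moment[7])
  expect_true(all(rep$pass[1:6]))
  # an all-ones intercept column has unit second moment by accident but is
  # still rejected by the centering check
  expect_false(check_standardized(cbind(z, 1))$pass[7])

  # n-1 standardization leaves a second moment of (n-1)/n
  s <- scale(matrix(rnorm(50), 10, 5))
  rep <- check_standardized(s)
  expect_false(any(rep$unit_moment))
  expect_equal(rep$second_moment, rep(0.9, 5), tolerance = 1e-12)
})

test_that("compute_gram matches its definition", {
  X <- make_orthonormal_design(9, 4)
  expect_equal(compute_gram(X), diag(4), tolerance = 1e-12)

  x1 <- zscore_columns(matrix(rnorm(10), 10, 1))
  X2 <- cbind(x1, -x1)
  expect_equal(compute_gram(X2)[1, 2], -1, tolerance = 1e-12)

  set.seed(3)
  X <- zscore_columns(matrix(rnorm(100), 20, 5))
  C <- compute_gram(X)
  naive <- matrix(0, 5, 5)
  for (j in 1:5) for (k in 1:5) naive[j, k] <- sum(X[, j] * X[, k]) / 20
  expect_equal(C, naive, tolerance = 1e-12)
  expect_equal(diag(C), rep(1, 5), tolerance = 1e-10)
  expect_true(all(abs(C) <= 1 + 1e-10))

  expect_error(compute_gram(X, max_bytes = 10), "estimate_memory")
  expect_error(compute_gram(matrix(rnorm(20), 10, 2)), "not z-scored")
})

test_that("compute_crossproducts matches its definition and ignores shifts", {
  set.seed(4)
  X <- zscore_columns(matrix(rnorm(120), 30, 4))
  C <- compute_gram(X)
  expect_equal(as.vector(compute_crossproducts(X, X[, 1, drop = FALSE])),
               C[, 1], tolerance = 1e-12)
  expect_equal(as.vector(compute_crossproducts(X, matrix(5, 30, 1))),
               rep(0, 4), tolerance = 1e-12)

  Y <- matrix(rnorm(90), 30, 3)
  cp <- compute_crossproducts(X, Y)
  naive <- matrix(0, 4, 3)
  for (j in 1:4) for (v in 1:3) naive[j, v] <- sum(X[, j] * Y[, v]) / 30
  expect_equal(cp, naive, tolerance = 1e-12)

  shifted <- sweep(Y, 2, c(10, -3, 0.5), "+")
  expect_equal(compute_crossproducts(X, shifted), cp, tolerance = 1e-10)
  expect_error(compute_crossproducts(X, Y[1:10, ]), "rows")
})

test_that("intercepts are exact column means", {
  expect_equal(compute_intercepts(matrix(7, 5, 1)), 7)
  y <- rnorm(10); y <- y - mean(y)
  expect_equal(compute_intercepts(cbind(y)), 0, tolerance = 1e-14)
})

test_that("lambda_start is the max absolute cross-product", {
  set.seed(5)
  X <- zscore_columns(matrix(rnorm(180), 30, 6))
  expect_equal(calculate_lambda_start(X, X[, 1, drop = FALSE]), 1,
               tolerance = 1e-12)
  expect_equal(calculate_lambda_start(X, matrix(2, 30, 1)), 0,
               tolerance = 1e-12)

  Y <- matrix(rnorm(120), 30, 4)
  brute <- 0
  for (j in 1:6) for (v in 1:4) {
    brute <- max(brute, abs(sum(X[, j] * Y[, v]) / 30))
  }
  expect_equal(calculate_lambda_start(X, Y), brute, tolerance = 1e-12)
  expect_equal(max(lambda_start_per_voxel(X, Y)),
               calculate_lambda_start(X, Y))
})

test_that("soft threshold implements sign(z) * max(|z| - t, 0)", {
  expect_equal(soft_threshold(0.5, 0.2), 0.3)
  expect_equal(soft_threshold(-0.5, 0.2), -0.3)
  expect_identical(soft_threshold(0.1, 0.2), 0)
  expect_equal(soft_threshold(c(1, -1, 0), 0.25), c(0.75, -0.75, 0))
  expect_error(soft_threshold(1, -0.1), "non-negative")
})

test_that("objective_value matches a term-by-term evaluation", {
  set.seed(6)
  X <- zscore_columns(matrix(rnorm(80), 20, 4))
  y <- rnorm(20)
  expect_equal(objective_value(X, y, numeric(4), mean(y), 0.3),
               sum((y - mean(y))^2) / 40, tolerance = 1e-12)

  beta <- c(0.5, 0, -1, 0.2)
  y2 <- as.vector(X %*% beta) + 2
  expect_equal(objective_value(X, y2, beta, 2, 0), 0, tolerance = 1e-12)

  lam <- 0.17
  r <- y2 - X %*% beta - 1.5
  byhand <- as.numeric(crossprod(r)) / (2 * 20) + lam * (0.5 + 1 + 0.2)
  expect_equal(objective_value(X, y2, beta, 1.5, lam), byhand,
               tolerance = 1e-12)
})

test_that("lambda sequence validation warns on non-decreasing order", {
  expect_silent(validate_lambda_seq(c(0.5, 0.25)))
  expect_warning(validate_lambda_seq(c(0.25, 0.5)), "not strictly decreasing")
  expect_warning(validate_lambda_seq(c(0.5, 0.5)), "not strictly decreasing")
  expect_error(validate_lambda_seq(numeric(0)), "empty")
  expect_error(validate_lambda_seq(c(0.5, -0.1)), "non-negative")
})

test_that("adding a constant to a response changes only the intercept", {
  set.seed(7)
  X <- zscore_columns(matrix(rnorm(40 * 8), 40, 8))
  Y <- matrix(rnorm(40 * 3), 40, 3)
  Ys <- Y + 100
  f1 <- cd_solve_path(X, Y, 2^-3)
  f2 <- cd_solve_path(X, Ys, 2^-3)
  expect_equal(f1$per_lambda[[1]]$values, f2$per_lambda[[1]]$values,
               tolerance = 1e-10)
  expect_equal(f2$intercepts, f1$intercepts + 100, tolerance = 1e-10)
  expect_equal(calculate_lambda_start(X, Y), calculate_lambda_start(X, Ys),
               tolerance = 1e-10)
})

test_that("residual means vanish at any converged fit", {
  set.seed(8)
  X <- zscore_columns(matrix(rnorm(50 * 10), 50, 10))
  Y <- matrix(rnorm(50 * 4), 50, 4)
  fit <- cd_solve_path(X, Y, 2^-4)
  B <- convert_betas_sparse_to_full(fit$per_lambda[[1]], 10)
  for (v in 1:4) {
    r <- Y[, v] - X %*% B[, v] - fit$intercepts[v]
    expect_lt(abs(mean(r)), 1e-6)
  }
})
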