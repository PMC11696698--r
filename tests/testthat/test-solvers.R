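test_that("OLS weights match hand-solved normal equations", {
  X <- diag(2); colnames(X) <- c("g1", "g2")
  Y <- matrix(c(3, 5), 1, dimnames = list(NULL, c("g1", "g2")))
  expect_equal(unname(unclass(ols_weights(Y, X)))[1, ], c(3, 5))

  # single prototype: projection onto (1, 2)
  X1 <- matrix(c(1, 2), 1)
  Y1 <- matrix(c(2, 4), 1)
  expect_equal(unname(unclass(ols_weights(Y1, X1)))[1, ], 2)

  # negative weights are possible
  X2 <- matrix(c(1, 0, 1, 1), 2, byrow = TRUE)
  Y2 <- matrix(c(0, 1), 1)
  expect_equal(unname(unclass(ols_weights(Y2, X2)))[1, ], c(-1, 1))

  expect_error(ols_weights(matrix(1, 1, 3), matrix(1, 1, 2)), "dimensions")
})

test_that("OLS residuals are orthogonal to the design; rank deficiency falls back to the pseudo-inverse", {
  for (seed in 1:5) {
    inst <- random_instance(seed, n_s = 4, n_c = 3, n_g = 6)
    M <- ols_weights(inst$Y, inst$X)
    expect_false(attr(M, "pseudo_inverse"))
    resid_proj <- (unclass(M) %*% inst$X - inst$Y) %*% t(inst$X)
    expect_lt(max(abs(resid_proj)), 1e-8)
  }

  # duplicated prototypes make X X' singular; min-norm solution splits
  # the weight equally between the duplicates
  X <- matrix(c(1, 0, 1, 0), 2, byrow = TRUE)
  Y <- matrix(c(4, 0), 1)
  M <- ols_weights(Y, X)
  expect_true(attr(M, "pseudo_inverse"))
  expect_equal(unname(unclass(M))[1, ], c(2, 2))
})

test_that("the ridge NNLS objective equals an elementwise summation oracle", {
  inst <- random_instance(7, n_s = 3, n_c = 2, n_g = 4)
  M <- matrix(runif(6), 3, 2)
  lam <- 0.3
  manual <- 0
  R <- inst$Y - M %*% inst$X
  for (i in seq_len(nrow(R))) for (j in seq_len(ncol(R))) {
    manual <- manual + 0.5 * R[i, j]^2
  }
  for (i in seq_len(nrow(M))) for (j in seq_len(ncol(M))) {
    manual <- manual + lam / 2 * M[i, j]^2
  }
  expect_equal(nnls_objective(M, inst$Y, inst$X, lam), manual)

  # perfect fit at lambda = 0 scores zero, M = 0 scores half the energy
  expect_equal(nnls_objective(M, M %*% inst$X, inst$X, 0), 0)
  expect_equal(nnls_objective(M * 0, inst$Y, inst$X, 0),
               0.5 * sum(inst$Y^2))
})

test_that("projected gradient solves hand-checked NNLS instances", {
  # identity design: unconstrained optimum is feasible
  X <- diag(2); colnames(X) <- NULL
  Y <- matrix(c(3, 5), 1)
  M <- nnls_weights(Y, X, lambda = 0, lr = 0.1, epochs = 200)
  expect_lt(max(abs(unclass(M) - Y)), 1e-6)

  # active constraint: optimum is (0, 0.5), found by grid/QP oracle
  X2 <- matrix(c(1, 0, 1, 1), 2, byrow = TRUE)
  Y2 <- matrix(c(0, 1), 1)
  M2 <- nnls_weights(Y2, X2, lambda = 0, lr = 0.1, epochs = 2000)
  expect_lt(max(abs(unclass(M2) - c(0, 0.5))), 1e-4)

  # overwhelming ridge squashes the weights to zero
  M3 <- nnls_weights(Y2, X2, lambda = 1e8, lr = 1e-9, epochs = 2000,
                     warm_start = FALSE)
  expect_lt(sqrt(sum(unclass(M3)^2)), 1e-3)

  # a step size far beyond the curvature blows the objective up and is
  # reported as an error rather than returned
  expect_error(
    nnls_weights(Y2 * 1e80, X2 * 1e80, lambda = 0, lr = 10,
                 warm_start = FALSE, epochs = 101),
    "lr"
  )
})

test_that("solver output is non-negative with a non-increasing objective trace", {
  for (seed in c(2, 12)) {
    inst <- random_instance(seed, n_s = 4, n_c = 3, n_g = 5)
    M <- nnls_weights(inst$Y, inst$X, lambda = 0.05, lr = 0.01,
                      epochs = 1000, warm_start = FALSE)
    expect_true(all(unclass(M) >= 0))
    expect_identical(attr(M, "estimator"), "NNLS")
    expect_identical(attr(M, "lambda_used"), 0.05)
    tr <- attr(M, "objective_trace")$objective
    expect_true(all(diff(tr) <= 1e-10))
  }
})

test_that("NNLS matches the active-set oracle and KKT conditions on random instances", {
  for (seed in 1:8) {
    inst <- random_instance(seed)
    M <- nnls_weights(inst$Y, inst$X, lambda = 0, lr = 0.01,
                      epochs = 10000, warm_start = TRUE)
    oracle <- oracle_nnls(inst$Y, inst$X, lambda = 0)
    expect_lt(
      abs(nnls_objective(unclass(M), inst$Y, inst$X, 0) -
            nnls_objective(oracle, inst$Y, inst$X, 0)),
      1e-4
    )
    expect_lt(kkt_violation(unclass(M), inst$Y, inst$X, 0), 1e-4)
  }
})

test_that("noiseless instances are recovered exactly and interior solutions match the ridge closed form", {
  # exact recovery: Y = M* X, M* >= 0, X full row rank
  withr::with_seed(31, {
    X <- matrix(rnorm(4 * 8), 4, 8)
    Mstar <- matrix(runif(3 * 4, 0.2, 1), 3, 4)
  })
  Y <- Mstar %*% X
  M <- nnls_weights(Y, X, lambda = 0, lr = 0.01, epochs = 5000)
  expect_lt(max(abs(unclass(M) - Mstar)), 1e-5)

  # strictly positive ridge solution equals Y X'(X X' + lambda I)^-1
  lam <- 0.5
  Mr <- nnls_weights(Y, X, lambda = lam, lr = 0.01, epochs = 10000)
  expect_true(all(unclass(Mr) > 0))
  expect_lt(max(abs(unclass(Mr) - ridge_closed_form(Y, X, lam))), 1e-4)
})

test_that("weight norm shrinks monotonically along the lambda grid", {
  inst <- random_instance(17, n_s = 4, n_c = 3, n_g = 6)
  norms <- vapply(seq(0, 0.2, by = 0.02), function(lam) {
    M <- nnls_weights(inst$Y, inst$X, lambda = lam, lr = 0.01,
                      epochs = 4000)
    sqrt(sum(unclass(M)^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("gene-split cross-validation selects and reports correctly", {
  sim <- simulate_mixture(n_types = 2, cells_per_type = 5, n_genes = 30,
                          n_spots = 8, noise = "none", seed = 5,
                          spot_depth = 100, cell_depth = 100)
  pp <- preprocess(sim$reference, sim$spatial, gene_top = 30)
  Y <- pp$spatial$counts; X <- pp$reference$counts

  # a single-value grid is selected without competition
  cv1 <- cv_lambda(Y, X, lambda_grid = 0.07, epochs = 50, seed = 2)
  expect_identical(cv1$selected_lambda, 0.07)

  # noiseless data: zero penalty reconstructs the held-out genes exactly
  cv <- cv_lambda(Y, X, lambda_grid = c(0, 0.1, 1), lr = 0.05,
                  epochs = 500, seed = 3)
  expect_identical(cv$selected_lambda, 0)
  expect_true(all(cv$results$mse >= 0))
  expect_identical(
    cv$selected_lambda,
    cv$summary$lambda[which.min(cv$summary$mean_mse)]
  )

  # fold assignment is a pure function of the seed
  cv_b <- cv_lambda(Y, X, lambda_grid = c(0, 0.1, 1), lr = 0.05,
                    epochs = 500, seed = 3)
  expect_equal(tidy(cv), tidy(cv_b))

  expect_identical(names(glance(cv)),
                   c("selected_lambda", "mean_mse", "n_fold", "n_lambda"))
  expect_error(cv_lambda(Y[, 1:3], X[, 1:3], n_fold = 5), "folds")
})
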