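test_that("weight aggregation computes per-type shares", {
  M <- matrix(c(1, 3), 1, dimnames = list("s1", NULL))
  P <- aggregate_nnls(M, c("A", "B"))
  expect_equal(unname(prop_mat(P)[1, ]), c(0.25, 0.75))
  expect_identical(names(P), c("spot", "A", "B"))

  # both prototypes the same type collapse to a single column of 1
  P2 <- aggregate_nnls(matrix(c(2, 2), 1), c("A", "A"))
  expect_equal(unname(prop_mat(P2)[1, 1]), 1)

  expect_error(aggregate_nnls(matrix(c(-1, 2), 1), c("A", "B")),
               "negative")
})

test_that("soft thresholding clamps per-type sums, not entries", {
  # type A sums to -1 (clamped), type B to 2
  M <- matrix(c(1, -2, 2), 1)
  P <- aggregate_sls(M, c("A", "A", "B"))
  expect_equal(unname(prop_mat(P)[1, ]), c(0, 1))

  # a negative entry inside a positive type sum must NOT be clamped:
  # A = 3 - 2 = 1, B = 3 -> (0.25, 0.75)
  M2 <- matrix(c(3, -2, 3), 1)
  P2 <- aggregate_sls(M2, c("A", "A", "B"))
  expect_equal(unname(prop_mat(P2)[1, ]), c(0.25, 0.75))
})

test_that("spots with no positive weight fall back to a uniform row with a warning", {
  M <- matrix(c(0, 0, 1, 3), 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), NULL))
  expect_warning(P <- aggregate_nnls(M, c("A", "B")), "uniform")
  expect_equal(unname(prop_mat(P)[1, ]), c(0.5, 0.5))
  expect_equal(unname(prop_mat(P)[2, ]), c(0.25, 0.75))
  expect_identical(attr(P, "fallback_spots"), 1L)

  Mneg <- matrix(c(-1, -2), 1)
  expect_warning(Pn <- aggregate_sls(Mneg, c("A", "B")), "uniform")
  expect_equal(unname(prop_mat(Pn)[1, ]), c(0.5, 0.5))
})

test_that("aggregation is invariant to column permutation and positive scaling", {
  withr::with_seed(8, {
    M <- matrix(runif(4 * 6), 4, 6)
    labels <- sample(c("A", "B", "C"), 6, replace = TRUE)
  })
  labels[1:3] <- c("A", "B", "C")  # ensure all types present
  base <- aggregate_nnls(M, labels)

  perm <- withr::with_seed(9, sample(6))
  expect_equal(
    prop_mat(aggregate_nnls(M[, perm], labels[perm])),
    prop_mat(base)
  )
  expect_equal(prop_mat(aggregate_nnls(3.7 * M, labels)), prop_mat(base))

  Mols <- M - 0.3
  expect_equal(
    prop_mat(aggregate_sls(0.01 * Mols, labels)),
    prop_mat(aggregate_sls(Mols, labels))
  )
})

test_that("every aggregated row lies on the probability simplex", {
  for (seed in 1:5) {
    inst <- random_instance(seed, n_s = 5, n_c = 4, n_g = 6)
    labels <- c("A", "B", "B", "C")
    Mn <- unclass(nnls_weights(inst$Y, inst$X, lambda = 0.01, lr = 0.01,
                               epochs = 500))
    P <- suppressWarnings(prop_mat(aggregate_nnls(Mn, labels)))
    expect_true(all(P >= 0))
    expect_true(all(abs(rowSums(P) - 1) < 1e-9))

    Ps <- suppressWarnings(prop_mat(aggregate_sls(
      unclass(ols_weights(inst$Y, inst$X)), labels
    )))
    expect_true(all(Ps >= 0))
    expect_true(all(abs(rowSums(Ps) - 1) < 1e-9))
  }
})

test_that("SLS and NNLS aggregations agree when OLS weights are already non-negative", {
  sim <- simulate_mixture(n_types = 3, cells_per_type = 4, n_genes = 50,
                          n_spots = 10, noise = "none", seed = 6)
  pp <- preprocess(sim$reference, sim$spatial, gene_top = 50)
  Y <- pp$spatial$counts; X <- pp$reference$counts
  Mols <- ols_weights(Y, X)
  expect_true(all(unclass(Mols) >= -1e-9))

  Mn <- nnls_weights(Y, X, lambda = 0, lr = 0.05, epochs = 3000)
  expect_lt(
    max(abs(prop_mat(aggregate_sls(Mols, pp$reference$cell_type)) -
              prop_mat(aggregate_nnls(Mn, pp$reference$cell_type)))),
    1e-4
  )
})

test_that("both estimators recover noiseless mixtures through the full pipeline", {
  sim <- simulate_mixture(n_types = 3, cells_per_type = 10, n_genes = 80,
                          n_spots = 20, noise = "none", seed = 11)
  pp <- preprocess(sim$reference, sim$spatial, gene_top = 80)

  fit_s <- deconv_sls(pp$reference, pp$spatial)
  fit_n <- deconv_nnls(pp$reference, pp$spatial, lambda = 0, lr = 0.01,
                       epochs = 1000)
  truth <- prop_mat(sim$truth)
  expect_lt(prop_rmse(fit_s, truth), 1e-6)
  expect_lt(prop_rmse(fit_n, truth), 1e-5)
  expect_identical(fit_s$cell_types, sort(unique(pp$reference$cell_type)))
  expect_gte(fit_s$elapsed, 0)

  # single-type reference: everything is that type
  one <- reference_profile(pp$reference$counts, rep("only", 30))
  fit1 <- deconv_sls(one, pp$spatial)
  expect_equal(unname(prop_mat(fit1$proportions)[, 1]),
               rep(1, 20))
})

test_that("deconv_nnls treats a length-1 grid as a scalar and is deterministic", {
  sim <- simulate_mixture(n_types = 2, cells_per_type = 5, n_genes = 30,
                          n_spots = 8, seed = 13)
  pp <- preprocess(sim$reference, sim$spatial, gene_top = 30)

  a <- deconv_nnls(pp$reference, pp$spatial, lambda = 0.1, epochs = 200,
                   seed = 1)
  b <- deconv_nnls(pp$reference, pp$spatial, lambda = c(0.1), epochs = 200,
                   seed = 1)
  expect_identical(a$proportions, b$proportions)
  expect_null(a$cv)

  cvfit <- deconv_nnls(pp$reference, pp$spatial, lambda = c(0, 0.1),
                       epochs = 100, seed = 4)
  expect_s3_class(cvfit$cv, "cv_report")
  expect_identical(cvfit$lambda, cvfit$cv$selected_lambda)
})

test_that("fit objects tidy, glance, and print coherently", {
  sim <- simulate_mixture(n_types = 3, cells_per_type = 4, n_genes = 40,
                          n_spots = 9, seed = 2)
  pp <- preprocess(sim$reference, sim$spatial, gene_top = 40)
  fit <- deconv_sls(pp$reference, pp$spatial)

  long <- tidy(fit)
  expect_identical(names(long), c("spot", "x", "y", "cell_type",
                                  "proportion"))
  expect_identical(nrow(long), 9L * 3L)
  sums <- tapply(long$proportion, long$spot, sum)
  expect_true(all(abs(sums - 1) < 1e-9))

  g <- glance(fit)
  expect_identical(g$method, "SLS")
  expect_identical(g$n_spots, 9L)
  expect_output(print(fit), "SLS")
})
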