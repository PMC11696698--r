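# Shared fixtures and independent oracles for the test suite.

# Small labelled reference: 3 cells x 2 genes, two types.
tiny_ref <- function() {
  m <- matrix(
    c(
      5, 1,
      4, 2,
      0, 6
    ),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("c1", "c2", "c3"), c("g1", "g2"))
  )
  reference_profile(m, c("A", "A", "B"))
}

tiny_spatial <- function() {
  m <- matrix(
    c(
      3, 1,
      1, 5
    ),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("s1", "s2"), c("g1", "g2"))
  )
  spatial_expression(m, data.frame(x = c(0, 1), y = c(0, 1)))
}

# Random dense regression instance with the dimensions used by the
# solver property tests. Gaussian entries keep the Gram matrix
# well-conditioned with high probability.
random_instance <- function(seed, n_s = NULL, n_c = NULL, n_g = NULL) {
  withr::with_seed(seed, {
    n_s <- n_s %||% sample(1:5, 1)
    n_c <- n_c %||% sample(1:4, 1)
    n_g <- n_g %||% sample(max(2, n_c):6, 1)
    list(
      Y = matrix(rnorm(n_s * n_g), n_s, n_g),
      X = matrix(rnorm(n_c * n_g), n_c, n_g)
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent NNLS oracle: Lawson-Hanson active-set solver applied per
# spot; the ridge term is folded in by augmenting the design with
# sqrt(lambda) * I.
oracle_nnls <- function(Y, X, lambda = 0) {
  C <- t(X)                                   # genes x cells
  if (lambda > 0) {
    C <- rbind(C, sqrt(lambda) * diag(nrow(X)))
  }
  out <- matrix(0, nrow(Y), nrow(X))
  for (i in seq_len(nrow(Y))) {
    d <- Y[i, ]
    if (lambda > 0) d <- c(d, rep(0, nrow(X)))
    out[i, ] <- pracma::lsqnonneg(C, d)$x
  }
  out
}

# Karush-Kuhn-Tucker residual of the NNLS objective at M: the most
# negative gradient on an active (zero) entry and the largest absolute
# gradient on a free (positive) entry, combined into one max violation.
kkt_violation <- function(M, Y, X, lambda = 0, eps = 1e-8) {
  G <- (M %*% X - Y) %*% t(X) + lambda * M
  active <- M <= eps
  viol_active <- if (any(active)) max(0, -min(G[active])) else 0
  viol_free <- if (any(!active)) max(abs(G[!active])) else 0
  max(viol_active, viol_free)
}

# Ridge closed form (no constraint): Y X' (X X' + lambda I)^-1.
ridge_closed_form <- function(Y, X, lambda) {
  Y %*% t(X) %*% solve(tcrossprod(X) + lambda * diag(nrow(X)))
}

# Matrix view of wide proportion tibbles, for elementwise assertions.
prop_mat <- function(P) {
  keep <- setdiff(names(P), c("spot", "x", "y"))
  m <- as.matrix(P[, keep, drop = FALSE])
  rownames(m) <- P$spot
  m
}

# Path to the installed command-line script plus an R_LIBS value that
# lets a child Rscript find the package under test.
cli_script <- function() {
  system.file("cli", "spotdecon.R", package = "spotdecon")
}

run_cli <- function(args) {
  res <- suppressWarnings(system2(
    file.path(R.home("bin"), "Rscript"), c(cli_script(), args),
    stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  ))
  list(status = attr(res, "status") %||% 0L, output = res)
}
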