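#' Ordinary least squares prototype weights
#'
#' Closed-form unconstrained estimate of the spot-by-prototype weight
#' matrix M in the linear mixing model Y = M X + E, where Y (spots x
#' genes) holds spatial counts and X (cells x genes) holds reference
#' prototypes: M = Y X' (X X')^-1. When X X' is singular or numerically
#' rank-deficient (common when prototypes are duplicated or genes are
#' few), the Moore-Penrose pseudo-inverse is used instead and the result
#' is flagged with attribute `pseudo_inverse = TRUE`. Entries may be
#' negative; see [aggregate_sls()] for the non-negative aggregation.
#'
#' @param Y Numeric matrix of spatial counts, spots x genes.
#' @param X Numeric matrix of reference counts, cells x genes.
#' @return Weight matrix (spots x cells) with attributes `estimator =
#'   "OLS"` and `pseudo_inverse`.
#' @export
ols_weights <- function(Y, X) {
  check_gene_dims(Y, X)
  xxt <- tcrossprod(X)
  xyt <- tcrossprod(X, Y)
  pinv <- FALSE
  sol <- if (rcond_ok(xxt)) {
    tryCatch(solve(xxt, xyt), error = function(e) NULL)
  } else {
    NULL
  }
  if (is.null(sol)) {
    pinv <- TRUE
    sol <- MASS::ginv(xxt) %*% xyt
  }
  M <- t(sol)
  dimnames(M) <- list(rownames(Y), rownames(X))
  structure(M, estimator = "OLS", pseudo_inverse = pinv)
}

rcond_ok <- function(a, tol = 1e-12) {
  if (nrow(a) == 1) return(a[1, 1] > tol)
  rc <- tryCatch(rcond(a), error = function(e) 0)
  is.finite(rc) && rc > tol
}

#' Ridge-penalized non-negative least squares objective
#'
#' The convex objective minimized by [nnls_weights()]:
#' `0.5 * ||Y - M X||_F^2 + (lambda / 2) * ||M||_F^2`.
#'
#' @param M Weight matrix, spots x cells.
#' @param Y Spatial counts, spots x genes.
#' @param X Reference counts, cells x genes.
#' @param lambda Non-negative ridge penalty.
#' @return A single non-negative number.
#' @export
nnls_objective <- function(M, Y, X, lambda = 0) {
  check_gene_dims(Y, X)
  stopifnot(nrow(M) == nrow(Y), ncol(M) == nrow(X), lambda >= 0)
  0.5 * sum((Y - M %*% X)^2) + lambda / 2 * sum(M^2)
}

#' Non-negative least squares weights by projected gradient descent
#'
#' Minimizes `0.5 ||Y - M X||_F^2 + (lambda/2) ||M||_F^2` subject to
#' `M >= 0` elementwise. The objective is convex, so projected gradient
#' descent -- a gradient step `M - lr * ((M X - Y) X' + lambda M)`
#' followed by clamping negative entries to zero -- converges to the
#' global constrained minimum for a sufficiently small step size.
#' Exactly `epochs` iterations are run (no early stopping), which makes
#' runs reproducible; the objective is recorded along the way so
#' convergence can be inspected.
#'
#' With `warm_start = TRUE` (default) the iterate starts from the
#' elementwise non-negative part of the OLS solution, `max(M_OLS, 0)`,
#' which is feasible and usually close to the optimum; otherwise it
#' starts from zero.
#'
#' @inheritParams nnls_objective
#' @param lambda Non-negative ridge penalty (single value).
#' @param lr Positive gradient step size (default 0.1). If iterates
#'   diverge to non-finite values the step size is too large for this
#'   problem's curvature and an error says so.
#' @param epochs Number of gradient iterations (default 1000).
#' @param warm_start Start from the clamped OLS solution (default `TRUE`).
#' @param trace_every Record the objective every this many epochs
#'   (default 100; the final objective is always recorded).
#' @return Non-negative weight matrix (spots x cells) with attributes
#'   `estimator = "NNLS"`, `lambda_used`, and `objective_trace` (tibble
#'   with columns `epoch`, `objective`).
#' @examples
#' X <- diag(2); colnames(X) <- c("g1", "g2")
#' Y <- matrix(c(3, 5), 1, dimnames = list(NULL, c("g1", "g2")))
#' nnls_weights(Y, X, lambda = 0)
#' @export
nnls_weights <- function(Y, X, lambda = 0.1, lr = 0.1, epochs = 1000,
                         warm_start = TRUE, trace_every = 100) {
  check_gene_dims(Y, X)
  stopifnot(length(lambda) == 1, lambda >= 0, lr > 0, epochs >= 1)
  xxt <- tcrossprod(X)          # cells x cells
  yxt <- tcrossprod(Y, X)       # spots x cells
  M <- if (isTRUE(warm_start)) {
    pmax(unclass_weights(ols_weights(Y, X)), 0)
  } else {
    matrix(0, nrow(Y), nrow(X))
  }
  trace_epochs <- unique(c(seq(0, epochs, by = trace_every), epochs))
  trace_obj <- rep(NA_real_, length(trace_epochs))
  objective_now <- function() {
    0.5 * sum((Y - M %*% X)^2) + lambda / 2 * sum(M^2)
  }
  ti <- 1
  trace_obj[ti] <- objective_now()
  for (e in seq_len(epochs)) {
    G <- M %*% xxt - yxt + lambda * M
    M <- pmax(M - lr * G, 0)
    if (ti < length(trace_epochs) && e == trace_epochs[ti + 1]) {
      ti <- ti + 1
      if (!all(is.finite(M))) {
        abort(paste(
          "Projected gradient iterates became non-finite;",
          "reduce the learning rate `lr`."
        ))
      }
      trace_obj[ti] <- objective_now()
      if (!is.finite(trace_obj[ti])) {
        abort(paste(
          "Objective overflowed during projected gradient descent;",
          "reduce the learning rate `lr`."
        ))
      }
    }
  }
  if (!all(is.finite(M))) {
    abort("Projected gradient iterates became non-finite; reduce `lr`.")
  }
  dimnames(M) <- list(rownames(Y), rownames(X))
  structure(
    M,
    estimator = "NNLS",
    lambda_used = lambda,
    objective_trace = tibble(epoch = trace_epochs, objective = trace_obj)
  )
}

unclass_weights <- function(M) {
  attributes(M) <- attributes(M)[c("dim", "dimnames")]
  M
}

#' Select the ridge penalty by gene-split cross-validation
#'
#' Genes (columns of both X and Y) are shuffled once with the given seed
#' and partitioned into `n_fold` contiguous blocks. For each candidate
#' `lambda` and each fold, the non-negative weights are fitted on the
#' training genes and scored on the held-out genes by the mean held-out
#' reconstruction error `0.5 / n_test * ||Y_test - M X_test||_F^2`. The
#' selected `lambda` minimizes the mean score over folds; ties go to the
#' smallest `lambda` (less shrinkage when indifferent).
#'
#' @inheritParams nnls_weights
#' @param lambda_grid Non-negative candidate penalties. Defaults to the
#'   11-point grid `seq(0, 0.2, by = 0.02)`.
#' @param n_fold Number of folds (default 5); must not exceed the number
#'   of genes.
#' @param seed Integer seed fixing the gene shuffle (default `NULL`:
#'   current RNG state).
#' @return A `cv_report` object: list with `results` (tibble of `lambda`,
#'   `fold`, `n_test`, `mse`), `summary` (tibble of `lambda`, `mean_mse`),
#'   `selected_lambda`, `lambda_grid`, `n_fold`, and `seed`. Supports
#'   [tidy()] and [glance()].
#' @export
cv_lambda <- function(Y, X, lambda_grid = seq(0, 0.2, by = 0.02),
                      n_fold = 5, lr = 0.1, epochs = 1000,
                      warm_start = TRUE, seed = NULL) {
  check_gene_dims(Y, X)
  stopifnot(length(lambda_grid) >= 1, all(lambda_grid >= 0), n_fold >= 2)
  n_g <- ncol(Y)
  if (n_g < n_fold) {
    abort(sprintf("Need at least %d genes for %d folds; have %d.",
                  n_fold, n_fold, n_g))
  }
  perm <- if (is.null(seed)) sample(n_g) else {
    withr::with_seed(seed, sample(n_g))
  }
  bounds <- round(seq(0, n_g, length.out = n_fold + 1))
  fold_cols <- lapply(seq_len(n_fold), function(f) {
    perm[(bounds[f] + 1):bounds[f + 1]]
  })
  grid <- sort(unique(lambda_grid))
  results <- purrr::map_dfr(seq_len(n_fold), function(f) {
    test <- fold_cols[[f]]
    train <- setdiff(seq_len(n_g), test)
    Ytr <- Y[, train, drop = FALSE]; Xtr <- X[, train, drop = FALSE]
    Yte <- Y[, test, drop = FALSE];  Xte <- X[, test, drop = FALSE]
    purrr::map_dfr(grid, function(lam) {
      M <- nnls_weights(Ytr, Xtr, lambda = lam, lr = lr, epochs = epochs,
                        warm_start = warm_start)
      tibble(
        lambda = lam, fold = f, n_test = length(test),
        mse = 0.5 / length(test) * sum((Yte - M %*% Xte)^2)
      )
    })
  })
  summary <- results |>
    dplyr::group_by(.data$lambda) |>
    dplyr::summarise(mean_mse = mean(.data$mse), .groups = "drop")
  best <- min(summary$lambda[summary$mean_mse == min(summary$mean_mse)])
  structure(
    list(
      results = results, summary = summary, selected_lambda = best,
      lambda_grid = grid, n_fold = n_fold, seed = seed
    ),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "<cv_report> %d-fold gene-split CV over %d lambda value(s)\n",
    x$n_fold, length(x$lambda_grid)
  ))
  cat(sprintf("  selected lambda: %g\n", x$selected_lambda))
  print(x$summary, n = length(x$lambda_grid))
  invisible(x)
}

#' @describeIn cv_lambda Per-(lambda, fold) held-out errors as a tibble.
#' @param x A `cv_report`.
#' @param ... Unused.
#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) x$results

#' @describeIn cv_lambda One-row summary with the selected lambda and its
#'   mean held-out error.
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) {
  tibble(
    selected_lambda = x$selected_lambda,
    mean_mse = x$summary$mean_mse[x$summary$lambda == x$selected_lambda],
    n_fold = x$n_fold,
    n_lambda = length(x$lambda_grid)
  )
}

check_gene_dims <- function(Y, X) {
  if (ncol(Y) != ncol(X)) {
    abort(sprintf(
      "Gene dimensions differ: spatial has %d columns, reference %d.",
      ncol(Y), ncol(X)
    ))
  }
  invisible(TRUE)
}
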