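#' Node-wise LASSO estimation of the dependence-coefficient matrix
#'
#' Each ICF category in turn is taken as the response of an L1-penalised
#' least-squares regression on all remaining categories,
#' \deqn{\hat\beta = \arg\min_\beta \frac{1}{2n}\|y - X\beta\|_2^2 +
#'   \lambda \|\beta\|_1,}
#' with the penalty chosen as the minimiser of the K-fold cross-validated
#' mean squared error (the "minimum MSE"). Stacking the per-response
#' coefficient vectors row-wise gives the p x p dependence-coefficient
#' matrix from which the dependency graph is built. Qualifiers are treated
#' as numeric, standardised to mean 0 / population SD 1, and coefficients
#' are reported on that standardised scale.
#'
#' @name lasso-engine
NULL

#' Soft-thresholding operator
#'
#' `sign(z) * max(|z| - gamma, 0)` -- the scalar kernel of coordinate
#' descent for the lasso.
#'
#' @param z numeric vector.
#' @param gamma non-negative threshold.
#' @return numeric vector.
#' @examples
#' soft_threshold(c(3, -0.5, -3), 1)   # 2, 0, -2
#' @export
soft_threshold <- function(z, gamma) {
  stopifnot(gamma >= 0)
  sign(z) * pmax(abs(z) - gamma, 0)
}

#' Estimation settings for the node-wise LASSO
#'
#' @param n_folds number of cross-validation folds (>= 2).
#' @param lambda_grid_size number of penalty values, log-spaced from
#'   `lambda_max` (the smallest penalty giving the all-zero model) down to
#'   `lambda_max * lambda_min_ratio`.
#' @param lambda_min_ratio ratio of smallest to largest grid value.
#' @param standardize standardise columns before regression (mean 0,
#'   population SD 1).
#' @param missing_policy how to handle 8/9 scores: impute the per-column
#'   median of observed values (default, preserves the design size) or drop
#'   patients with any missing score.
#' @param cv_seed seed keying the deterministic fold shuffle.
#' @param zero_tol coefficients with absolute value at or below this are
#'   treated as exact zeros (edge absence).
#' @param tol coordinate-descent convergence tolerance.
#' @param max_iter coordinate-descent iteration cap per penalty value.
#' @return list of class `estimation_config`.
#' @export
estimation_config <- function(n_folds = 10L, lambda_grid_size = 100L,
                              lambda_min_ratio = 1e-3, standardize = TRUE,
                              missing_policy = c("impute_column_median",
                                                 "drop_patient"),
                              cv_seed = 1L, zero_tol = 1e-8,
                              tol = 1e-10, max_iter = 100000L) {
  stopifnot(n_folds >= 2, lambda_grid_size >= 1,
            lambda_min_ratio > 0, lambda_min_ratio < 1, zero_tol > 0)
  structure(list(n_folds = as.integer(n_folds),
                 lambda_grid_size = as.integer(lambda_grid_size),
                 lambda_min_ratio = lambda_min_ratio,
                 standardize = isTRUE(standardize),
                 missing_policy = match.arg(missing_policy),
                 cv_seed = as.integer(cv_seed), zero_tol = zero_tol,
                 tol = tol, max_iter = as.integer(max_iter)),
            class = "estimation_config")
}

#' Standardise columns of a (possibly incomplete) numeric matrix
#'
#' Missing entries (NA) are first filled per `missing_policy` -- by default
#' with the per-column median of the observed values -- then each column is
#' centred and scaled to population SD 1 (divide by `sqrt(mean((x-mean)^2))`,
#' matching the `1/2n` loss convention).
#'
#' @param x numeric matrix, NAs allowed.
#' @param missing_policy see [estimation_config()].
#' @return list: `x` (standardised matrix), `center`, `scale` (per column),
#'   `kept_rows` (row indices retained; differs from the input only under
#'   `drop_patient`).
#' @export
standardize_columns <- function(x, missing_policy = "impute_column_median") {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  kept <- seq_len(nrow(x))
  if (anyNA(x)) {
    if (missing_policy == "drop_patient") {
      kept <- which(stats::complete.cases(x))
      x <- x[kept, , drop = FALSE]
    } else {
      for (j in seq_len(ncol(x))) {
        nas <- is.na(x[, j])
        if (any(nas)) {
          obs <- x[!nas, j]
          if (!length(obs)) {
            stop("category '", colnames(x)[j], "' has no observed values",
                 call. = FALSE)
          }
          x[nas, j] <- median(obs)
        }
      }
    }
  }
  center <- colMeans(x)
  xc <- sweep(x, 2L, center)
  scl <- sqrt(colMeans(xc^2))
  zero <- which(scl == 0)
  if (length(zero)) {
    nm <- colnames(x)[zero[1L]]
    stop("category '", if (is.null(nm)) zero[1L] else nm,
         "' is constant and cannot enter a regression", call. = FALSE)
  }
  list(x = sweep(xc, 2L, scl, "/"), center = center, scale = scl,
       kept_rows = kept)
}

#' Penalty grid for a standardised problem
#'
#' Log-spaced from `lambda_max = max_j |x_j' y| / n` (the smallest penalty
#' at which the solution is identically zero) down by `lambda_min_ratio`.
#'
#' @param x,y standardised predictors and response.
#' @param config an [estimation_config()].
#' @return decreasing numeric vector.
#' @export
lambda_grid <- function(x, y, config = estimation_config()) {
  lambda_max <- max(abs(crossprod(x, y))) / nrow(x)
  if (lambda_max == 0) lambda_max <- 1e-3  # y orthogonal to every predictor
  exp(seq(log(lambda_max), log(lambda_max * config$lambda_min_ratio),
          length.out = config$lambda_grid_size))
}

#' Fit a lasso at fixed penalty
#'
#' Coordinate descent on centred inputs; the returned solution satisfies the
#' Karush-Kuhn-Tucker conditions to within the convergence tolerance (see
#' [kkt_violation()]).
#'
#' @param x predictor matrix (centred; typically standardised).
#' @param y response vector (centred).
#' @param lambda non-negative penalty.
#' @param config an [estimation_config()] (for `tol` / `max_iter`).
#' @return named coefficient vector (length `ncol(x)`).
#' @export
lasso_fit <- function(x, y, lambda, config = estimation_config()) {
  stopifnot(lambda >= 0, all(is.finite(x)), all(is.finite(y)))
  beta <- cd_lasso_path(as.matrix(x), as.numeric(y), lambda,
                        config$tol, config$max_iter)[, 1L]
  names(beta) <- colnames(x)
  beta
}

#' Largest KKT violation of a candidate lasso solution
#'
#' For the objective `(1/2n)||y - X b||^2 + lambda ||b||_1` the optimum
#' satisfies `x_j'(y - Xb)/n = lambda * sign(b_j)` on the active set and
#' `|x_j'(y - Xb)/n| <= lambda` elsewhere; the return value is the largest
#' deviation from these conditions (0 at an exact optimum).
#'
#' @param x,y the design and response used in the fit.
#' @param beta candidate coefficients.
#' @param lambda the penalty used.
#' @return non-negative scalar.
#' @export
kkt_violation <- function(x, y, beta, lambda) {
  g <- as.numeric(crossprod(x, y - x %*% beta)) / nrow(x)
  active <- beta != 0
  max(c(0,
        abs(g[active] - lambda * sign(beta[active])),
        pmax(abs(g[!active]) - lambda, 0)))
}

#' Select the penalty by cross-validated minimum MSE
#'
#' Patients are shuffled deterministically by `cv_seed` and cut into
#' `n_folds` contiguous blocks; for each fold the lasso path is fitted on
#' the remaining folds (warm starts along the grid) and held-out squared
#' errors are pooled over all patients. The selected penalty minimises the
#' pooled MSE; exact ties break toward the larger (sparser) penalty.
#'
#' @param x,y standardised predictors and response.
#' @param config an [estimation_config()].
#' @param lambda optional penalty grid (defaults to [lambda_grid()]).
#' @return list: `lambda` (the selected value), `mmse` (the minimised CV
#'   MSE), `cv_mse` (per-grid-value), `lambda_grid`, `beta` (coefficients of
#'   the full-data fit at the selected penalty).
#' @export
select_lambda_cv <- function(x, y, config = estimation_config(),
                             lambda = NULL) {
  x <- as.matrix(x); y <- as.numeric(y)
  n <- nrow(x)
  if (config$n_folds > n) stop("more folds than rows", call. = FALSE)
  if (is.null(lambda)) lambda <- lambda_grid(x, y, config)
  set.seed(config$cv_seed)
  perm <- sample.int(n)
  # contiguous blocks of the shuffled indices
  sizes <- tabulate(cut(seq_len(n), config$n_folds, labels = FALSE),
                    config$n_folds)
  fold_of <- integer(n)
  fold_of[perm] <- rep(seq_len(config$n_folds), sizes)
  if (min(sizes) < 2L) stop("degenerate fold with < 2 rows", call. = FALSE)
  sq_err <- matrix(NA_real_, n, length(lambda))
  for (k in seq_len(config$n_folds)) {
    test <- which(fold_of == k)
    beta_path <- cd_lasso_path(x[-test, , drop = FALSE], y[-test], lambda,
                               config$tol, config$max_iter)
    pred <- x[test, , drop = FALSE] %*% beta_path
    sq_err[test, ] <- (y[test] - pred)^2
  }
  cv_mse <- colMeans(sq_err)
  best <- which(cv_mse <= min(cv_mse))[1L]  # grid is decreasing: first = largest
  beta <- cd_lasso_path(x, y, lambda[seq_len(best)],
                        config$tol, config$max_iter)[, best]
  names(beta) <- colnames(x)
  list(lambda = lambda[best], mmse = cv_mse[best], cv_mse = cv_mse,
       lambda_grid = lambda, beta = beta)
}

#' Estimate the dependence-coefficient matrix of a cohort
#'
#' Runs one cross-validated node-wise lasso per category: row `i` of the
#' result holds the coefficients of the regression with category `i` as
#' response (so entry `(i, j)` is the weight of predictor `j` in predicting
#' `i`); the diagonal is identically zero. Scores 8/9 are mapped to missing
#' and handled per `missing_policy`. Categories with constant observed
#' scores cannot enter any regression; they are dropped with a warning and
#' recorded in the `excluded` attribute.
#'
#' @param cohort a [qualifier_matrix()] (or plain numeric matrix with
#'   category colnames; values 8/9 are treated as missing).
#' @param config an [estimation_config()].
#' @return numeric p x p matrix of class `dependence_matrix` with attributes
#'   `fits` (per-response penalty and minimised CV MSE), `excluded`
#'   (constant categories dropped) and `config`.
#' @export
estimate_dependence_matrix <- function(cohort, config = estimation_config()) {
  x <- as.matrix(unclass(cohort))
  storage.mode(x) <- "double"
  if (ncol(x) < 2L) stop("need at least 2 categories", call. = FALSE)
  # key the CV fold assignment to sorted patient ids, so permuting the input
  # rows cannot change the estimate
  if (!is.null(rownames(x))) x <- x[order(rownames(x)), , drop = FALSE]
  x[x %in% c(8, 9)] <- NA_real_
  if (config$missing_policy == "drop_patient") {
    x <- x[stats::complete.cases(x), , drop = FALSE]
  } else if (anyNA(x)) {
    for (j in seq_len(ncol(x))) {
      nas <- is.na(x[, j])
      if (any(nas)) x[nas, j] <- median(x[!nas, j])
    }
  }
  const <- which(apply(x, 2L, function(v) length(unique(v)) == 1L))
  if (length(const)) {
    warning("excluding constant categor",
            if (length(const) > 1) "ies: " else "y: ",
            paste(colnames(x)[const], collapse = ", "), call. = FALSE)
    x <- x[, -const, drop = FALSE]
  }
  codes <- colnames(x)
  p <- length(codes)
  std <- if (config$standardize) standardize_columns(x)$x else
    sweep(x, 2L, colMeans(x))
  D <- matrix(0, p, p, dimnames = list(codes, codes))
  fits <- data.frame(response = codes, lambda = NA_real_, mmse = NA_real_)
  for (i in seq_len(p)) {
    sel <- select_lambda_cv(std[, -i, drop = FALSE], std[, i], config)
    beta <- sel$beta
    beta[abs(beta) <= config$zero_tol] <- 0
    D[i, -i] <- beta
    fits$lambda[i] <- sel$lambda
    fits$mmse[i] <- sel$mmse
  }
  structure(D, class = c("dependence_matrix", "matrix", "array"),
            fits = fits, excluded = colnames(cohort)[const], config = config)
}

#' Write a dependence matrix as dense and sparse CSV
#'
#' @param D a `dependence_matrix` (rows = response codes).
#' @param dense_path,sparse_path output CSVs; the sparse edge list keeps
#'   entries with `|value| > zero_tol` as `response,predictor,coefficient`.
#' @param zero_tol threshold for the sparse export.
#' @return invisibly, the sparse edge data frame.
#' @export
write_dependence_matrix <- function(D, dense_path, sparse_path,
                                    zero_tol = 1e-8) {
  df <- data.frame(response = rownames(D), unclass(D), check.names = FALSE)
  write.csv(df, dense_path, row.names = FALSE, quote = FALSE)
  idx <- which(abs(D) > zero_tol, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  edges <- data.frame(response = rownames(D)[idx[, 1L]],
                      predictor = colnames(D)[idx[, 2L]],
                      coefficient = D[idx])
  write.csv(edges, sparse_path, row.names = FALSE, quote = FALSE)
  invisible(edges)
}

#' Read back a dense dependence-matrix CSV
#'
#' @param path CSV written by [write_dependence_matrix()].
#' @return a `dependence_matrix`.
#' @export
read_dependence_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  structure(m, class = c("dependence_matrix", "matrix", "array"))
}
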