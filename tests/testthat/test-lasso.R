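test_that("soft-thresholding closed form", {
  expect_equal(soft_threshold(3, 1), 2)
  expect_equal(soft_threshold(-0.5, 1), 0)
  expect_equal(soft_threshold(-3, 1), -2)
  expect_error(soft_threshold(1, -0.1))
})

test_that("column standardisation: convention, idempotence, imputation", {
  s <- standardize_columns(matrix(c(1, 2, 3), ncol = 1))
  expect_equal(as.numeric(s$x), c(-1, 0, 1) / sqrt(2 / 3))  # population SD

  twice <- standardize_columns(s$x)
  expect_equal(twice$x, s$x, tolerance = 1e-12)

  m <- matrix(c(1, 1, 1, 1, 0, 1, 2, 3), 4,
              dimnames = list(NULL, c("b410", "b415")))
  expect_error(standardize_columns(m), "'b410' is constant")

  # hand computation: observed {1,2,4}, median 2 fills the gap
  col <- matrix(c(1, 2, NA, 4), ncol = 1)
  filled <- c(1, 2, 2, 4)
  expect_equal(as.numeric(standardize_columns(col)$x),
               (filled - mean(filled)) / sqrt(mean((filled - mean(filled))^2)))

  # drop_patient removes the incomplete row instead
  s2 <- standardize_columns(matrix(c(1, 2, NA, 4), ncol = 1), "drop_patient")
  expect_equal(s2$kept_rows, c(1L, 2L, 4L))
})

test_that("lasso limits: null model above lambda_max, OLS at lambda 0", {
  inst <- random_instance(30, 4, seed = 1)
  lmax <- max(abs(crossprod(inst$x, inst$y))) / nrow(inst$x)
  expect_true(all(lasso_fit(inst$x, inst$y, lmax * 1.0001) == 0))
  ols <- as.numeric(solve(crossprod(inst$x), crossprod(inst$x, inst$y)))
  expect_equal(unname(lasso_fit(inst$x, inst$y, 0)), ols, tolerance = 1e-6)
})

test_that("coordinate descent agrees with the brute-force oracle", {
  set.seed(99)
  for (i in 1:12) {
    n <- sample(10:25, 1); p <- sample(2:6, 1)
    inst <- random_instance(n, p, seed = 1000 + i)
    lmax <- max(abs(crossprod(inst$x, inst$y))) / n
    lam <- runif(1, 0.05, 0.9) * lmax
    beta <- unname(lasso_fit(inst$x, inst$y, lam))
    expect_equal(beta, oracle_lasso(inst$x, inst$y, lam), tolerance = 1e-6)
    expect_lt(kkt_violation(inst$x, inst$y, beta, lam), 1e-6)
  }
})

test_that("coordinate descent agrees with glmnet at matched objective", {
  library(glmnet)
  for (i in 1:5) {
    inst <- random_instance(40, 6, seed = 200 + i)
    lam <- 0.1
    ours <- unname(lasso_fit(inst$x, inst$y, lam))
    theirs <- as.numeric(coef(glmnet(inst$x, inst$y, alpha = 1,
                                     lambda = lam, standardize = FALSE,
                                     intercept = FALSE, thresh = 1e-14)))[-1]
    expect_equal(ours, theirs, tolerance = 1e-4)
  }
})

test_that("sparsity is monotone along the penalty path", {
  for (seed in 1:5) {
    inst <- random_instance(50, 6, seed = 300 + seed)
    lam <- lambda_grid(inst$x, inst$y, estimation_config())
    path <- icfnet:::cd_lasso_path(inst$x, inst$y, lam, 1e-10, 100000L)
    nnz <- colSums(abs(path) > 1e-8)
    expect_true(all(diff(nnz) >= 0))  # grid is decreasing in lambda
  }
})

test_that("CV penalty selection is deterministic and signal-sensitive", {
  cfg <- quick_config(cv_seed = 7)
  # pure noise: empty or near-empty model
  set.seed(21)
  x <- matrix(rnorm(200 * 5), 200, 5)
  y <- rnorm(200)
  std <- standardize_columns(x)$x
  yc <- (y - mean(y)) / sqrt(mean((y - mean(y))^2))
  sel <- select_lambda_cv(std, yc, cfg)
  expect_lte(sum(abs(sel$beta) > 1e-8), 1L)
  sel2 <- select_lambda_cv(std, yc, cfg)
  expect_identical(sel$lambda, sel2$lambda)
  expect_identical(sel$mmse, sel2$mmse)
  expect_gte(sel$mmse, 0)

  # strong signal: the driving predictor is selected
  y2 <- 0.9 * x[, 1] + rnorm(200, sd = 0.3)
  y2c <- (y2 - mean(y2)) / sqrt(mean((y2 - mean(y2))^2))
  sel3 <- select_lambda_cv(std, y2c, cfg)
  expect_gt(abs(sel3$beta[1]), 0.5)
  expect_lt(sel3$mmse, sel$mmse)
})

test_that("dependence matrix: shape, exclusions, independence, chain", {
  # two independent noise categories stay unconnected
  co <- generate_cohort(noise_spec(500, 2, seed = 6))
  D <- estimate_dependence_matrix(co$matrix, quick_config())
  expect_equal(dim(D), c(2L, 2L))
  expect_true(all(D == 0))

  # planted chain: direct edges present, skip edge conditionally absent
  codes <- c("b130", "b134", "b144")
  co <- generate_cohort(chain_spec(1000, codes, c(0.9, 0.9), seed = 1,
                                   noise_sd = 1))
  D <- estimate_dependence_matrix(co$matrix, quick_config())
  expect_gt(abs(D["b134", "b130"]), 0.2)
  expect_gt(abs(D["b144", "b134"]), 0.2)
  expect_lt(abs(D["b144", "b130"]), 0.1)
  expect_true(all(diag(D) == 0))

  # constant categories are excluded with a warning
  m <- unclass(co$matrix)
  m <- cbind(m, d999 = 2L)
  expect_warning(D2 <- estimate_dependence_matrix(m, quick_config()),
                 "constant categor.*d999")
  expect_equal(dim(D2), c(3L, 3L))
  expect_equal(attr(D2, "excluded"), "d999")
})

test_that("row permutation leaves the dependence matrix unchanged", {
  co <- generate_cohort(chain_spec(200, c("b130", "b134", "b144"),
                                   c(0.8, 0.8), seed = 14))
  cfg <- quick_config(cv_seed = 3)
  D1 <- estimate_dependence_matrix(co$matrix, cfg)
  perm <- sample(nrow(co$matrix))
  D2 <- estimate_dependence_matrix(co$matrix[perm, ], cfg)
  expect_identical(unclass(D1), unclass(D2))
})
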