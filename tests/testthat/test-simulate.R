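test_that("edge-free latents are independent noise", {
  spec <- noise_spec(n = 5000, p = 5, seed = 11)
  x <- generate_latent(spec)
  expect_equal(dim(x), c(5000L, 5L))
  expect_true(all(abs(colMeans(x)) < 0.1))
  r <- cor(x)
  expect_true(all(abs(r[upper.tri(r)]) < 0.1))
})

test_that("a single edge reproduces its closed-form correlation", {
  # noise-free limit: child equals parent
  sch <- tiny_schema(c("b130", "b134"))
  e <- data.frame(source = "b130", target = "b134", weight = 1)
  spec <- synthetic_spec(100, sch, e, noise_sd = 1e-9, seed = 2)
  x <- generate_latent(spec)
  expect_equal(x[, "b134"], x[, "b130"], tolerance = 1e-6)

  # weight 0.8, noise 0.6: corr = 0.8 / sqrt(0.64 + 0.36) = 0.8
  e$weight <- 0.8
  spec <- synthetic_spec(5000, sch, e, noise_sd = 0.6, seed = 3)
  x <- generate_latent(spec)
  expect_equal(cor(x[, "b130"], x[, "b134"]), 0.8, tolerance = 0.05)
})

test_that("cyclic planted structures are rejected with an explicit cycle", {
  sch <- tiny_schema(c("b130", "b134", "b144"))
  e <- data.frame(source = c("b130", "b134", "b144"),
                  target = c("b134", "b144", "b130"),
                  weight = 0.5)
  expect_error(synthetic_spec(10, sch, e) |> generate_latent(),
               "cyclic.*b1[34]", ignore.case = TRUE)
})

test_that("discretisation maps latent bins to 0..4 monotonically", {
  cuts <- c(-1.5, -0.5, 0.5, 1.5)
  expect_identical(discretize_latent(0, cuts), 2L)
  expect_identical(discretize_latent(-99, cuts), 0L)
  expect_identical(discretize_latent(99, cuts), 4L)
  expect_error(discretize_latent(0, c(1, 1, 2, 3)), "strictly increasing")

  # bin masses match the analytic N(0,1) probabilities
  set.seed(5)
  z <- rnorm(1000)
  scores <- discretize_latent(z, cuts)
  probs <- diff(c(0, pnorm(cuts), 1))
  obs <- tabulate(scores + 1L, 5L) / 1000
  expect_true(all(abs(obs - probs) < 4 * sqrt(probs * (1 - probs) / 1000)))
})

test_that("missingness injection hits its nominal rates", {
  v <- matrix(2L, 120, 46,
              dimnames = list(sprintf("P%03d", 1:120), load_schema("cihd")$code))
  expect_identical(unclass(inject_missing(v, 0, 0, seed = 1))[, ], v[, ])
  expect_true(all(unclass(inject_missing(v, 1, 0, seed = 1)) == 8L))
  m <- inject_missing(v, 0.05, 0.02, seed = 9)
  frac8 <- mean(unclass(m) == 8L)
  expect_lt(abs(frac8 - 0.05), 3 * sqrt(0.05 * 0.95 / length(v)))
  expect_error(inject_missing(v, 0.7, 0.6, seed = 1), "sum to at most 1")
})

test_that("cohort generation is deterministic in the master seed", {
  spec <- chain_recovery_spec(120, seed = 4)
  spec$missing_rate_8 <- 0.05
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$matrix, b$matrix)
  expect_true(all(unclass(a$matrix) %in% c(0:4, 8L, 9L)))
  expect_equal(dim(a$matrix), c(120L, 10L))

  spec2 <- spec; spec2$seed <- 5L
  expect_false(identical(unclass(generate_cohort(spec2)$matrix),
                         unclass(a$matrix)))
})

test_that("synthetic specs round-trip through YAML", {
  spec <- chain_recovery_spec(50, seed = 8)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_synthetic_spec(spec, f)
  back <- read_synthetic_spec(f, spec$schema)
  expect_equal(back$edges, spec$edges)
  expect_equal(back$thresholds, spec$thresholds)
  expect_identical(generate_cohort(back)$matrix, generate_cohort(spec)$matrix)
})
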