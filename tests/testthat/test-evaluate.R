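test_that("evaluation report matches hand-enumerated values", {
  r <- evaluate_predictions(c(1, 2), c(2, 1))
  expect_equal(r$mse, 1)
  expect_equal(r$mspe, 1)
  expect_equal(r$msne, 1)
  expect_equal(r$over_rate, 0.5)
  expect_equal(r$under_rate, 0.5)

  r <- evaluate_predictions(c(3, 3, 3), c(3, 3, 3))
  expect_equal(r$mse, 0)
  expect_equal(r$n_exact, 3)
  expect_equal(r$over_rate, 0)
  expect_false(r$r2_defined)
  expect_true(is.na(r$r2))

  # per-element: residuals 1, 2, -1, 0
  r <- evaluate_predictions(c(0, 0, 0, 0), c(1, 2, -1, 0))
  expect_equal(r$mspe, (1 + 4) / 2)
  expect_equal(r$msne, 1)
  expect_equal(r$over_rate, 0.5)
  expect_equal(r$under_rate, 0.25)
  expect_equal(r$n_exact, 1)
  expect_error(evaluate_predictions(1:3, 1:2), "length")
})

test_that("side decomposition n*mse = n_over*mspe + n_under*msne holds", {
  set.seed(21)
  for (i in 1:40) {
    n <- sample(1:50, 1)
    y <- rnorm(n)
    p <- y + sample(c(-1, 0, 1), n, TRUE) * rexp(n)
    r <- evaluate_predictions(y, p)
    expect_equal(r$n * r$mse, r$n_over * r$mspe + r$n_under * r$msne)
    expect_equal(r$n_over + r$n_under + r$n_exact, n)
    # mse is the weighted mean of mspe and msne only when no residual
    # is exactly zero
    if (r$n_over > 0 && r$n_under > 0 && r$n_exact == 0) {
      expect_gte(r$mse, min(r$mspe, r$msne))
      expect_lte(r$mse, max(r$mspe, r$msne))
    }
  }
})

test_that("evaluation is invariant to permuting the pairs", {
  set.seed(22)
  y <- rnorm(30); p <- rnorm(30)
  perm <- sample(30)
  expect_equal(unclass(evaluate_predictions(y, p)),
               unclass(evaluate_predictions(y[perm], p[perm])))
})

test_that("under-predicted day counting is strict and matches a recount", {
  expect_equal(count_underpredicted_days(c(10, 20, 30), c(10, 15, 35)), 1)
  expect_equal(count_underpredicted_days(c(1, 2), c(5, 5)), 0)
  set.seed(23)
  y <- rpois(534, 100); p <- y + rnorm(534, 0, 20)
  expect_equal(count_underpredicted_days(y, p), sum(p < y))
})

test_that("bias-variance harness recovers degenerate and closed-form cases", {
  grid <- matrix(seq(0, 1, length.out = 50))
  zero_gen <- function(s) gen_linear(50, 1, 0, 0, noise_sd = 0, seed = s)
  zero_fit <- function(X, y) structure(list(), class = "zero_model")
  assign("predict.zero_model",
         function(object, newdata = NULL, ...) rep(0, nrow(newdata)),
         envir = globalenv())
  on.exit(rm("predict.zero_model", envir = globalenv()), add = TRUE)
  bv <- bias_variance_estimate(zero_gen, zero_fit, 10, grid,
                               truth = function(g) rep(0, nrow(g)),
                               seed = 1)
  expect_equal(bv$bias_squared, 0)
  expect_equal(bv$variance, 0)

  # a predictor that outputs one pure noise draw per replicate has
  # across-replicate variance equal to the noise variance
  noise_gen <- function(s) gen_linear(20, 1, 0, 0, noise_sd = 1, seed = s)
  noise_fit <- function(X, y) structure(list(v = y[1]),
                                        class = "const_model")
  assign("predict.const_model",
         function(object, newdata = NULL, ...) rep(object$v,
                                                   nrow(newdata)),
         envir = globalenv())
  on.exit(rm("predict.const_model", envir = globalenv()), add = TRUE)
  bv <- bias_variance_estimate(noise_gen, noise_fit, 100, grid,
                               truth = function(g) rep(0, nrow(g)),
                               seed = 2)
  expect_lt(abs(bv$variance - 1), 3 * sqrt(2 / 99))
})

test_that("unregularized least squares is nearly unbiased on linear truth", {
  grid <- matrix(seq(0, 1, length.out = 200))
  gen <- function(s) gen_linear(1000, 1, 2, 1, noise_sd = 0.5, seed = s)
  bv <- bias_variance_estimate(gen, function(X, y) oblm(X, y), 100, grid,
                               truth = function(g) 2 * g[, 1] + 1,
                               seed = 3)
  expect_lt(bv$bias_squared, 1e-2 * 0.5^2)
  expect_identical(length(bv$r2), 100L)
})

test_that("bias-variance estimates are reproducible under a fixed seed", {
  grid <- matrix(seq(0, 1, length.out = 20))
  gen <- function(s) gen_linear(100, 1, 2, 0, noise_sd = 0.5, seed = s)
  fit <- function(X, y) oblm(X, y)
  a <- bias_variance_estimate(gen, fit, 5, grid,
                              truth = function(g) 2 * g[, 1], seed = 4)
  b <- bias_variance_estimate(gen, fit, 5, grid,
                              truth = function(g) 2 * g[, 1], seed = 4)
  expect_identical(a$predictions, b$predictions)
  expect_error(
    bias_variance_estimate(gen, function(X, y) stop("boom"), 3, grid,
                           truth = function(g) 2 * g[, 1], seed = 5),
    "replicate 1")
})

test_that("evaluation reports serialize to JSON", {
  r <- evaluate_predictions(c(1, 2, 3), c(1.5, 2, 2.5))
  js <- jsonlite::fromJSON(write_report_json(r))
  expect_equal(js$mse, r$mse)
  expect_equal(js$n_over, r$n_over)
  f <- tempfile(fileext = ".json")
  write_report_json(r, f)
  expect_equal(jsonlite::fromJSON(f)$under_rate, r$under_rate)
})
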