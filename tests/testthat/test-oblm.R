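test_that("noise-free linear data is interpolated exactly", {
  d <- gen_linear(50, 1, 2, 1, noise_sd = 0, seed = 1)
  fit <- oblm(d$X, d$y)
  expect_equal(unname(fit$W), 2, tolerance = 1e-6)
  expect_equal(fit$b, 1, tolerance = 1e-6)
  expect_equal(predict(fit, d$X), d$y, tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("beta = 0 reduces to the closed-form least-squares solution", {
  for (s in 1:5) {
    dd <- if (s %% 2) 1 else 4
    cf <- if (dd == 1) 2 else c(1.5, -2, 1, 0.5)
    d <- gen_linear(500, dd, cf, 1, noise_sd = 0.5, seed = s)
    fit <- oblm(d$X, d$y)
    ls <- stats::lm.fit(cbind(1, d$X), d$y)$coefficients
    expect_equal(unname(c(fit$b, fit$W)), unname(ls), tolerance = 1e-6)
  }
})

test_that("ridge-penalized fit matches the closed-form weighted solve", {
  d <- gen_linear(300, 2, c(1, -1), 0, noise_sd = 0.3, seed = 6)
  l2 <- 0.05
  fit <- oblm(d$X, d$y, lambda2 = l2)
  Xt <- cbind(d$X, 1)
  th <- solve(crossprod(Xt) / nrow(Xt) + diag(c(l2, l2, 0)),
              crossprod(Xt, d$y) / nrow(Xt))
  expect_equal(unname(c(fit$W, fit$b)), unname(drop(th)),
               tolerance = 1e-6)
})

test_that("fitted parameters match a brute-force grid + simplex oracle", {
  x <- c(0, 1, 2, 3, 4)
  y <- c(0, 1, 2, 3, 10)
  fit <- oblm(matrix(x), y, bias_penalty("under", beta = 5))
  oracle <- grid_oracle_fit(x, y, beta = 5, direction = "under")
  expect_equal(unname(c(fit$W, fit$b)), oracle, tolerance = 1e-3)
})

test_that("predict applies W and b row-wise and validates dimensions", {
  d <- gen_linear(30, 1, 2, 1, noise_sd = 0, seed = 2)
  fit <- oblm(d$X, d$y)
  expect_equal(predict(fit, matrix(c(0, 1))), c(1, 3), tolerance = 1e-6)
  expect_error(predict(fit, matrix(0, 2, 3)), "columns")
  expect_equal(predict(fit), fitted(fit))
})

test_that("the formula interface agrees with the matrix interface", {
  d <- gen_linear(120, 2, c(1, 2), -1, noise_sd = 0.2, seed = 3)
  df <- data.frame(d$X, y = d$y)
  f1 <- oblm(y ~ x1 + x2, df, penalty = bias_penalty("over", beta = 0.5))
  f2 <- oblm(d$X, d$y, penalty = bias_penalty("over", beta = 0.5))
  expect_equal(coef(f1), coef(f2))
  expect_equal(unname(predict(f1, df[1:5, ])),
               predict(f2, d$X[1:5, ]))
})

test_that("input validation rejects malformed data", {
  expect_error(oblm(matrix(1:4, 2), 1:3), "equal")
  expect_error(oblm(matrix(c(1, NA), 2, 1), c(1, 2)), "finite")
  expect_error(oblm(matrix(numeric(0), 0, 1), numeric(0)), "empty")
})

test_that("penalized-side count is non-increasing along the beta grid", {
  d <- gen_linear(300, 2, c(1.5, -2), 1, noise_sd = 0.5, seed = 7)
  for (dir in c("over", "under")) {
    counts <- sapply(c(0, 0.01, 0.1, 1, 10), function(b) {
      e <- residuals(oblm(d$X, d$y, bias_penalty(dir, beta = b)))
      if (dir == "over") sum(e > 0) else sum(e < 0)
    })
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("the recorded cost path is non-increasing", {
  d <- gen_linear(200, 1, 2, 1, noise_sd = 0.5, seed = 8)
  fit <- oblm(d$X, d$y, bias_penalty("over", beta = 2))
  expect_true(all(diff(fit$cost_path) <= 0))
  expect_gte(fit$final_cost, 0)
})

test_that("identical data and config give bit-identical fits", {
  d <- gen_linear(150, 2, c(1, -1), 0, noise_sd = 0.4, seed = 9)
  f1 <- oblm(d$X, d$y, bias_penalty("under", beta = 0.3))
  f2 <- oblm(d$X, d$y, bias_penalty("under", beta = 0.3))
  expect_identical(f1$W, f2$W)
  expect_identical(f1$b, f2$b)
})

test_that("an l1 penalty shrinks coefficients and is flagged convergent", {
  d <- gen_linear(300, 2, c(1, 0), 0, noise_sd = 0.3, seed = 10)
  f0 <- oblm(d$X, d$y)
  f1 <- oblm(d$X, d$y, lambda1 = 0.2)
  expect_lt(sum(abs(f1$W)), sum(abs(f0$W)))
  expect_true(is.logical(f1$converged))
})

test_that("residuals respect the requested sign convention", {
  d <- gen_linear(40, 1, 2, 0, noise_sd = 0.5, seed = 11)
  fit <- oblm(d$X, d$y)
  expect_equal(residuals(fit), fitted(fit) - d$y)
  expect_equal(residuals(fit, type = "response"), d$y - fitted(fit))
})
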