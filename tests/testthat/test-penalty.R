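test_that("penalty configuration enforces its invariants", {
  pen <- bias_penalty("over", p = 2, beta = 1)
  expect_s3_class(pen, "bias_penalty")
  expect_identical(pen$normalization, "mean")
  expect_error(bias_penalty("over", beta = -0.1), "beta")
  expect_error(bias_penalty("over", p = 0.5), "p")
  expect_error(bias_penalty("sideways"), "arg")
})

test_that("signed residuals follow the over-prediction sign convention", {
  expect_equal(signed_residuals(c(2, 1), c(1, 2)), c(1, -1))
  expect_equal(signed_residuals(c(0, 0), c(0, 0)), c(0, 0))
  expect_equal(signed_residuals(5, 3), 2)
  expect_error(signed_residuals(1:3, 1:2), "length")
  expect_error(signed_residuals(c(1, NA), c(0, 0)), "finite")
  expect_error(signed_residuals(numeric(0), numeric(0)), "at least one")
})

test_that("psi matches the formula and an independent per-element loop", {
  sum_over <- bias_penalty("over", normalization = "sum")
  sum_under <- bias_penalty("under", normalization = "sum")
  expect_equal(psi(c(1, -1), sum_over), 2)
  expect_equal(psi(c(1, -1), sum_under), 2)
  expect_equal(psi(c(0, 0, 0), bias_penalty("over")), 0)
  expect_equal(psi(c(0, 0, 0), sum_under), 0)
  # independently recomputed: (2*0.25 + 2*4 + 0)/3
  e <- c(0.5, 2, -3)
  expect_equal(psi(e, bias_penalty("over")), 8.5 / 3)
  expect_equal(psi(e, bias_penalty("over")),
               psi_ref(e, "over", 2, "mean"))
  # odd exponent stays well defined through |e|^p
  expect_equal(psi(e, bias_penalty("under", p = 3)),
               psi_ref(e, "under", 3, "mean"))
})

test_that("psi is non-negative and zero iff nothing on the penalized side", {
  set.seed(101)
  for (i in 1:50) {
    e <- rnorm(sample(1:30, 1))
    dir <- sample(c("over", "under"), 1)
    pen <- bias_penalty(dir, p = sample(c(1, 1.5, 2, 3), 1),
                        normalization = sample(c("sum", "mean"), 1))
    v <- psi(e, pen)
    expect_gte(v, 0)
    on_side <- if (dir == "over") any(e > 0) else any(e < 0)
    expect_identical(v > 0, on_side)
  }
})

test_that("psi has mirror symmetry and p=2 homogeneity", {
  set.seed(202)
  for (i in 1:25) {
    e <- rnorm(10)
    for (norm in c("sum", "mean")) {
      expect_identical(psi(e, bias_penalty("over", normalization = norm)),
                       psi(-e, bias_penalty("under", normalization = norm)))
    }
    c_scale <- runif(1, 0.1, 5)
    expect_equal(psi(c_scale * e, bias_penalty("over")),
                 c_scale^2 * psi(e, bias_penalty("over")))
  }
})

test_that("psi_gradient matches hand values and finite differences", {
  sum_over <- bias_penalty("over", normalization = "sum")
  expect_equal(psi_gradient(1, sum_over), 4)
  expect_equal(psi_gradient(-1, sum_over), 0)
  expect_equal(psi_gradient(0, sum_over), 0)
  set.seed(303)
  for (i in 1:100) {
    e <- rnorm(12)
    e[abs(e) < 1e-4] <- 1e-2  # keep clear of the kink for differencing
    dir <- sample(c("over", "under"), 1)
    pen <- bias_penalty(dir, p = sample(c(1.5, 2, 3), 1),
                        normalization = sample(c("sum", "mean"), 1))
    fd <- fd_gradient(function(v) psi(v, pen), e)
    expect_equal(psi_gradient(e, pen), fd, tolerance = 1e-6)
  }
})

test_that("total_cost combines the base loss and the weighted penalty", {
  expect_equal(total_cost(1, c(0, 0), bias_penalty("over", beta = 7)), 1)
  expect_equal(total_cost(0, c(1, -1),
                          bias_penalty("over", beta = 1,
                                       normalization = "sum")), 1)
  e <- c(0.5, 2, -3)
  expect_equal(total_cost(2.5, e, bias_penalty("over", beta = 0.4)),
               2.5 + 0.2 * psi_ref(e, "over", 2, "mean"))
  expect_equal(total_cost(3.3, e, bias_penalty("under", beta = 0)), 3.3)
})

test_that("midpoint convexity check accepts convex, rejects concave", {
  expect_true(check_midpoint_convexity(function(w) w^2, -1, 1))
  expect_false(check_midpoint_convexity(function(w) -w^2, -1, 1))
  expect_error(check_midpoint_convexity(function(w) NaN, -1, 1),
               "non-finite")
})

test_that("the full regularized linear cost is midpoint convex", {
  d <- gen_linear(150, 2, c(1, -1), 0.5, noise_sd = 0.4, seed = 404)
  set.seed(405)
  for (beta in c(0, 1)) {
    cost <- full_cost_fn(d$X, d$y, bias_penalty("over", beta = beta))
    for (i in 1:100) {
      a <- runif(3, -10, 10)
      b <- runif(3, -10, 10)
      expect_true(check_midpoint_convexity(cost, a, b))
    }
  }
})

test_that("loss plugin reduces to MSE at beta 0 and differentiates cleanly", {
  plug0 <- make_loss_plugin(bias_penalty("under", beta = 0))
  set.seed(506)
  y <- rnorm(20); p <- rnorm(20)
  expect_equal(plug0$value(p, y), mean((p - y)^2))
  plug <- make_loss_plugin(bias_penalty("under", beta = 0.5))
  expect_equal(plug$value(y, y), 0)
  expect_equal(plug$gradient(y, y), rep(0, 20))
  fd <- fd_gradient(function(v) plug$value(v, y), p)
  expect_equal(plug$gradient(p, y), fd, tolerance = 1e-6)
})
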