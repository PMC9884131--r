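# Independent oracles used across the suite. These are deliberately naive
# (per-element loops, finite differences, dense grid search) and share no
# code with the package internals they check.

# penalty value by explicit per-element loop
psi_ref <- function(e, direction, p, normalization) {
  total <- 0
  for (ei in e) {
    s <- if (direction == "over") sign(ei) + 1 else -sign(ei) + 1
    total <- total + s * abs(ei)^p
  }
  if (normalization == "mean") total / length(e) else total
}

# central finite differences of a scalar- or vector-input function
fd_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(j) {
    xp <- x; xm <- x
    xp[j] <- xp[j] + h
    xm[j] <- xm[j] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# dense grid search refined by Nelder-Mead, for 2-parameter univariate
# penalized least-squares problems; independent of the package solver
grid_oracle_fit <- function(x, y, beta, direction, p = 2,
                            normalization = "mean",
                            w_range = c(-5, 10), b_range = c(-10, 10)) {
  obj <- function(th) {
    e <- th[1] * x + th[2] - y
    s <- if (direction == "over") sign(e) + 1 else -sign(e) + 1
    pen <- sum(s * abs(e)^p)
    if (normalization == "mean") pen <- pen / length(e)
    mean((e)^2) + beta / 2 * pen
  }
  grid <- expand.grid(W = seq(w_range[1], w_range[2], by = 0.1),
                      b = seq(b_range[1], b_range[2], by = 0.1))
  start <- as.numeric(grid[which.min(apply(grid, 1, obj)), ])
  stats::optim(start, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-15, maxit = 10000))$par
}

# seeded row subsample, local to a test
with_seed_rows <- function(n, k, seed) {
  set.seed(seed)
  sample.int(n, k)
}

# primal epsilon-insensitive objective at an e1071 linear-kernel solution
e1071_linear_solution <- function(X, y, C, epsilon) {
  m <- e1071::svm(X, y, type = "eps-regression", kernel = "linear",
                  cost = C, epsilon = epsilon, scale = FALSE,
                  tolerance = 1e-8)
  list(w = drop(t(m$coefs) %*% m$SV), b = -m$rho)
}

# full optimism-regularized linear-regression cost at parameters th on a
# fixed dataset, written independently of oblm internals
full_cost_fn <- function(X, y, penalty, lambda2 = 0) {
  function(th) {
    d <- ncol(X)
    e <- drop(X %*% th[seq_len(d)]) + th[d + 1] - y
    mean(e^2) + penalty$beta / 2 *
      psi_ref(e, penalty$direction, penalty$p, penalty$normalization) +
      lambda2 * sum(th[seq_len(d)]^2)
  }
}
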