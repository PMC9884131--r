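#' Optimism-bias regularized linear regression
#'
#' Fits \eqn{h(x) = W^\top x + b} by minimizing the convex objective
#' \deqn{\frac{1}{n}\sum_i (h(X_i)-y_i)^2 + \frac{\beta}{2}\Psi(h(X)-y)
#'   + \lambda_2 \|W\|_2^2 + \lambda_1 \|W\|_1,}
#' where \eqn{\Psi} is the one-sided optimism-bias penalty of
#' [bias_penalty()]. With \code{beta = 0} and no classical penalty the fit
#' reduces to ordinary least squares. For \eqn{p = 2} the objective is
#' continuously differentiable and piecewise quadratic, and the returned
#' parameters are the global minimum (the objective is strictly convex in
#' the predictions).
#'
#' The solver runs BFGS with analytic gradients from the deterministic
#' start \eqn{W = 0}, \eqn{b = \bar y}, then (for \eqn{p = 2},
#' \eqn{\lambda_1 = 0}) polishes with exact active-set weighted
#' least-squares steps under a backtracking line search until the gradient
#' norm falls below \code{tol}. With \eqn{\lambda_1 > 0} the \eqn{\ell_1}
#' term is handled by its subgradient inside BFGS and convergence is
#' assessed on the minimal-norm subgradient.
#'
#' @param x a numeric feature matrix (n rows, d columns), or a formula.
#' @param y numeric response vector of length n.
#' @param penalty a [bias_penalty()] object; the default (beta = 0)
#'   disables the optimism term.
#' @param lambda2,lambda1 non-negative ridge and lasso weights on \code{W}
#'   (the intercept is never penalized).
#' @param tol convergence tolerance on the gradient norm.
#' @param maxit maximum number of solver iterations.
#' @param ... passed between methods.
#' @return An object of class \code{"oblm"}: a list with components
#'   \code{W}, \code{b}, \code{coefficients} (intercept first),
#'   \code{fitted.values}, \code{residuals} (prediction minus target),
#'   \code{converged}, \code{n_iterations}, \code{final_cost},
#'   \code{cost_path} (objective after each accepted solver stage),
#'   \code{penalty} and the call.
#' @examples
#' d <- gen_linear(200, 1, coefficients = 2, intercept = 1,
#'                 noise_sd = 0.3, seed = 1)
#' fit <- oblm(d$X, d$y, bias_penalty("over", beta = 1))
#' coef(fit)
#' sum(residuals(fit) > 0)  # over-predictions are suppressed
#' @seealso [obsvr()], [evaluate_predictions()], [bias_penalty()]
#' @export
oblm <- function(x, ...) UseMethod("oblm")

#' @rdname oblm
#' @param formula,data model formula and data frame for the formula
#'   interface.
#' @export
oblm.formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  icpt <- match("(Intercept)", colnames(X))
  if (!is.na(icpt)) X <- X[, -icpt, drop = FALSE]
  fit <- oblm.default(X, y, ...)
  fit$call <- match.call()
  fit$terms <- attr(mf, "terms")
  fit
}

#' @rdname oblm
#' @export
oblm.default <- function(x, y, penalty = bias_penalty(), lambda2 = 0,
                         lambda1 = 0, tol = 1e-8, maxit = 10000, ...) {
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("nrow(x) must equal length(y)")
  if (nrow(X) < 1L) stop("empty data")
  if (!all(is.finite(X)) || !all(is.finite(y))) stop("inputs must be finite")
  stopifnot_penalty(penalty)
  stopifnot(lambda2 >= 0, lambda1 >= 0, tol > 0, maxit >= 1)

  sol <- solve_penalized_ls(X, y, penalty, lambda2, lambda1, tol, maxit)
  W <- sol$W
  names(W) <- colnames(X) %||% paste0("x", seq_along(W))
  fitted <- drop(X %*% W) + sol$b
  structure(list(
    W = W, b = sol$b,
    coefficients = c("(Intercept)" = sol$b, W),
    fitted.values = fitted,
    residuals = fitted - y,
    converged = sol$converged,
    n_iterations = sol$n_iterations,
    final_cost = sol$final_cost,
    cost_path = sol$cost_path,
    gradient_norm = sol$gradient_norm,
    penalty = penalty, lambda2 = lambda2, lambda1 = lambda1,
    tol = tol, maxit = maxit,
    n = nrow(X), d = ncol(X),
    call = match.call()
  ), class = "oblm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# objective, prediction-space gradient, and parameter-space gradient of the
# penalized least-squares problem; theta = c(W, b)
oblm_objective <- function(theta, X, y, penalty, lambda2, lambda1) {
  d <- ncol(X)
  W <- theta[seq_len(d)]
  b <- theta[d + 1L]
  e <- drop(X %*% W) + b - y
  mean(e^2) + penalty$beta / 2 * psi(e, penalty) +
    lambda2 * sum(W^2) + lambda1 * sum(abs(W))
}

oblm_gradient <- function(theta, X, y, penalty, lambda2, lambda1) {
  d <- ncol(X)
  W <- theta[seq_len(d)]
  b <- theta[d + 1L]
  e <- drop(X %*% W) + b - y
  gpred <- 2 * e / length(e) + penalty$beta / 2 * psi_gradient(e, penalty)
  c(drop(crossprod(X, gpred)) + 2 * lambda2 * W + lambda1 * sign(W),
    sum(gpred))
}

# minimal-norm subgradient norm: for W_j = 0 the l1 term contributes the
# interval [-lambda1, lambda1], so the smooth part may be shrunk toward 0
oblm_subgrad_norm <- function(theta, X, y, penalty, lambda2, lambda1) {
  g <- oblm_gradient(theta, X, y, penalty, lambda2, lambda1)
  if (lambda1 > 0) {
    d <- ncol(X)
    at_zero <- which(theta[seq_len(d)] == 0)
    g[at_zero] <- sign(g[at_zero]) * pmax(abs(g[at_zero]) - lambda1, 0)
  }
  sqrt(sum(g^2))
}

solve_penalized_ls <- function(X, y, penalty, lambda2, lambda1, tol, maxit) {
  d <- ncol(X)
  n <- nrow(X)
  fn <- function(th) oblm_objective(th, X, y, penalty, lambda2, lambda1)
  gr <- function(th) oblm_gradient(th, X, y, penalty, lambda2, lambda1)

  theta <- c(rep(0, d), mean(y))
  cost_path <- fn(theta)
  iters <- 0L

  opt <- stats::optim(theta, fn, gr, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-14))
  iters <- iters + opt$counts[["function"]]
  if (opt$value <= cost_path[length(cost_path)]) {
    theta <- opt$par
    cost_path <- c(cost_path, opt$value)
  }

  # exact polish for the piecewise-quadratic smooth case
  if (penalty$p == 2 && lambda1 == 0) {
    Xt <- cbind(X, 1)
    pen_scale <- if (penalty$normalization == "mean") 1 / n else 1
    D <- diag(c(rep(lambda2, d), 0), d + 1L)
    for (k in seq_len(50L)) {
      cur <- cost_path[length(cost_path)]
      e <- drop(Xt %*% theta) - y
      on_side <- if (penalty$direction == "over") e > 0 else e < 0
      cw <- 1 / n + penalty$beta * pen_scale * on_side
      A <- crossprod(Xt, Xt * cw) + D
      rhs <- crossprod(Xt, cw * y)
      target <- tryCatch(drop(solve(A, rhs)), error = function(err) NULL)
      if (is.null(target)) break
      dir <- target - theta
      step <- 1
      new_cost <- fn(theta + dir)
      while (new_cost > cur && step > 1e-12) {
        step <- step / 2
        new_cost <- fn(theta + step * dir)
      }
      iters <- iters + 1L
      if (new_cost > cur || !is.finite(new_cost)) break
      theta <- theta + step * dir
      cost_path <- c(cost_path, new_cost)
      if (sqrt(sum(gr(theta)^2)) <= tol) break
      if (cur - new_cost < 1e-15 * max(1, abs(cur))) break
    }
  }

  gnorm <- oblm_subgrad_norm(theta, X, y, penalty, lambda2, lambda1)
  theta <- unname(theta)
  list(W = theta[seq_len(d)], b = theta[d + 1L],
       converged = gnorm <= tol, n_iterations = iters,
       final_cost = cost_path[length(cost_path)],
       cost_path = cost_path, gradient_norm = gnorm)
}

#' @export
print.oblm <- function(x, digits = max(3L, getOption("digits") - 3L), ...) {
  cat("Optimism-bias regularized linear model\n")
  cat("  penalty:", x$penalty$direction, "side, beta =", x$penalty$beta,
      ", p =", x$penalty$p, "\n")
  cat("Coefficients:\n")
  print(round(x$coefficients, digits))
  if (!x$converged)
    cat("Warning: solver did not reach gradient tolerance (norm ",
        format(x$gradient_norm), ")\n", sep = "")
  invisible(x)
}

#' @export
coef.oblm <- function(object, ...) object$coefficients

#' Predict from a fitted optimism-bias linear model
#'
#' @param object an [oblm()] fit.
#' @param newdata feature matrix (or data frame for formula fits); if
#'   omitted, fitted values are returned.
#' @param ... unused.
#' @return Numeric vector \code{newdata \%*\% W + b}.
#' @export
predict.oblm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  if (!is.null(object$terms) && is.data.frame(newdata)) {
    X <- stats::model.matrix(stats::delete.response(object$terms), newdata)
    icpt <- match("(Intercept)", colnames(X))
    if (!is.na(icpt)) X <- X[, -icpt, drop = FALSE]
  } else {
    X <- as.matrix(newdata)
  }
  if (ncol(X) != length(object$W))
    stop("newdata has ", ncol(X), " columns; model expects ",
         length(object$W))
  drop(X %*% object$W) + object$b
}

#' Residuals of an optimism-bias linear model
#'
#' @param object an [oblm()] fit.
#' @param type \code{"prediction"} returns the package's signed convention
#'   \eqn{\hat y - y} (positive = over-prediction); \code{"response"}
#'   returns the classical \eqn{y - \hat y}.
#' @param ... unused.
#' @export
residuals.oblm <- function(object, type = c("prediction", "response"), ...) {
  type <- match.arg(type)
  if (type == "prediction") object$residuals else -object$residuals
}

#' @export
fitted.oblm <- function(object, ...) object$fitted.values

#' @export
summary.oblm <- function(object, ...) {
  rep <- evaluate_predictions(object$fitted.values - object$residuals,
                              object$fitted.values)
  structure(list(fit = object, report = rep), class = "summary.oblm")
}

#' @export
print.summary.oblm <- function(x, ...) {
  print(x$fit)
  cat(sprintf("n = %d, iterations = %d, final cost = %.6g\n",
              x$fit$n, x$fit$n_iterations, x$fit$final_cost))
  print(x$report)
  invisible(x)
}
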