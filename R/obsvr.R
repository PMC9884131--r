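#' Optimism-bias regularized support vector regression
#'
#' Fits epsilon-insensitive support vector regression in its unconstrained
#' primal form, with the optimism-bias term added:
#' \deqn{\frac{1}{2}\|\omega\|^2 + C \sum_i \max(0, |h(X_i)-y_i| - \epsilon)
#'   + \frac{\beta}{2}\Psi(h(X)-y).}
#' The hinge term is the unconstrained equivalent of the classical slack
#' formulation (\eqn{\xi^+,\xi^-}): residuals smaller than \eqn{\epsilon}
#' in magnitude are ignored. The intercept \eqn{b} is not penalized.
#'
#' For \code{kernel = "linear"}, \eqn{h(x) = w^\top x + b}. For
#' \code{kernel = "rbf"}, the model is expressed on the training Gram
#' matrix, \eqn{h(x) = \sum_j \alpha_j K(x_j, x) + b} with
#' \eqn{K(u,v) = \exp(-\gamma\|u-v\|^2)} and
#' \eqn{\|\omega\|^2 = \alpha^\top K \alpha}.
#'
#' The solver minimizes a graduated smoothing of the two plus-functions
#' (quadratic smoothing of width \code{mu}, decreased over stages) with
#' BFGS and analytic gradients; the reported \code{final_cost} is the exact
#' non-smoothed objective. The procedure is deterministic.
#'
#' @param x feature matrix (n x d).
#' @param y numeric response of length n.
#' @param C positive error-weight of the hinge term.
#' @param epsilon non-negative half-width of the insensitivity tube.
#' @param kernel \code{"linear"} or \code{"rbf"}.
#' @param gamma RBF width; defaults to \code{1/ncol(x)}.
#' @param penalty a [bias_penalty()] object.
#' @param tol gradient-norm tolerance on the final smoothed stage;
#'   \code{converged} is also set when the final BFGS stage reports
#'   convergence (the exact objective is non-smooth, so its gradient norm
#'   need not vanish at the minimum).
#' @param maxit maximum BFGS iterations per stage.
#' @return An object of class \code{"obsvr"} with components \code{w} (or
#'   \code{alpha} and \code{x_train} for the RBF kernel), \code{b},
#'   \code{final_cost}, \code{cost_path}, \code{converged},
#'   \code{n_iterations}, \code{fitted.values}, \code{residuals} and the
#'   configuration.
#' @examples
#' d <- gen_linear(60, 1, coefficients = 2, intercept = 1,
#'                 noise_sd = 0.2, seed = 3)
#' fit <- obsvr(d$X, d$y, C = 1, epsilon = 0.1)
#' mean((predict(fit, d$X) - d$y)^2)
#' @seealso [oblm()], [svr_primal_cost()]
#' @export
obsvr <- function(x, y, C = 1, epsilon = 0.1,
                  kernel = c("linear", "rbf"), gamma = NULL,
                  penalty = bias_penalty(), tol = 1e-6, maxit = 2000) {
  kernel <- match.arg(kernel)
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("nrow(x) must equal length(y)")
  if (!all(is.finite(X)) || !all(is.finite(y))) stop("inputs must be finite")
  stopifnot_penalty(penalty)
  stopifnot(C > 0, epsilon >= 0, tol > 0)
  if (kernel == "rbf") {
    if (is.null(gamma)) gamma <- 1 / ncol(X)
    if (gamma <= 0) stop("'gamma' must be > 0 for the rbf kernel")
  }

  n <- nrow(X)
  if (kernel == "linear") {
    B <- X                       # design in coefficient space
    Q <- NULL                    # norm term is sum(w^2)
  } else {
    B <- rbf_gram(X, X, gamma)   # predictions = K alpha + b
    Q <- B                       # norm term is alpha' K alpha
  }
  npar <- ncol(B)

  exact_cost <- function(th) {
    coefs <- th[seq_len(npar)]
    e <- drop(B %*% coefs) + th[npar + 1L] - y
    norm2 <- if (is.null(Q)) sum(coefs^2) else drop(coefs %*% Q %*% coefs)
    norm2 / 2 + C * sum(pmax(0, abs(e) - epsilon)) +
      penalty$beta / 2 * psi(e, penalty)
  }

  theta <- c(rep(0, npar), stats::median(y))
  cost_path <- exact_cost(theta)
  iters <- 0L
  gnorm <- Inf
  last_code <- 1L
  mu_grid <- max(1, stats::sd(y)) * c(1e-1, 1e-3, 1e-6)
  for (mu in mu_grid) {
    fn <- function(th) {
      coefs <- th[seq_len(npar)]
      e <- drop(B %*% coefs) + th[npar + 1L] - y
      norm2 <- if (is.null(Q)) sum(coefs^2) else drop(coefs %*% Q %*% coefs)
      norm2 / 2 + C * sum(smooth_plus(e - epsilon, mu) +
                          smooth_plus(-e - epsilon, mu)) +
        penalty$beta / 2 * psi(e, penalty)
    }
    gr <- function(th) {
      coefs <- th[seq_len(npar)]
      e <- drop(B %*% coefs) + th[npar + 1L] - y
      ge <- C * (smooth_plus_d(e - epsilon, mu) -
                 smooth_plus_d(-e - epsilon, mu)) +
        penalty$beta / 2 * psi_gradient(e, penalty)
      gnorm_part <- if (is.null(Q)) coefs else drop(Q %*% coefs)
      c(gnorm_part + drop(crossprod(B, ge)), sum(ge))
    }
    opt <- stats::optim(theta, fn, gr, method = "BFGS",
                        control = list(maxit = maxit, reltol = 1e-14))
    iters <- iters + opt$counts[["function"]]
    last_code <- opt$convergence
    cand_cost <- exact_cost(opt$par)
    if (cand_cost <= cost_path[length(cost_path)]) {
      theta <- opt$par
      cost_path <- c(cost_path, cand_cost)
    }
    gnorm <- sqrt(sum(gr(theta)^2))
  }

  coefs <- theta[seq_len(npar)]
  fitted <- drop(B %*% coefs) + theta[npar + 1L]
  out <- list(
    b = theta[npar + 1L],
    kernel = kernel, C = C, epsilon = epsilon, penalty = penalty,
    final_cost = cost_path[length(cost_path)], cost_path = cost_path,
    converged = last_code == 0L || gnorm <= max(tol, 1e-6),
    n_iterations = iters,
    gradient_norm = gnorm,
    fitted.values = fitted, residuals = fitted - y,
    n = n, d = ncol(X), call = match.call()
  )
  if (kernel == "linear") {
    out$w <- stats::setNames(coefs, colnames(X) %||%
                               paste0("x", seq_len(ncol(X))))
  } else {
    out$alpha <- coefs
    out$x_train <- X
    out$gamma <- gamma
  }
  structure(out, class = "obsvr")
}

# quadratic smoothing of max(0, u): C1, exact outside (0, mu)
smooth_plus <- function(u, mu) {
  ifelse(u <= 0, 0, ifelse(u >= mu, u - mu / 2, u^2 / (2 * mu)))
}
smooth_plus_d <- function(u, mu) {
  ifelse(u <= 0, 0, ifelse(u >= mu, 1, u / mu))
}

rbf_gram <- function(A, B, gamma) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

#' Primal SVR objective at given linear parameters
#'
#' Evaluates \eqn{\frac{1}{2}\|w\|^2 + C\sum_i\max(0,|x_i^\top w + b - y_i|
#' - \epsilon) + (\beta/2)\Psi} for an arbitrary linear parameter pair,
#' e.g. to compare solutions across solvers.
#'
#' @param w coefficient vector; @param b intercept.
#' @param x,y training data.
#' @param C,epsilon SVR parameters.
#' @param penalty a [bias_penalty()] object.
#' @export
svr_primal_cost <- function(w, b, x, y, C, epsilon,
                            penalty = bias_penalty()) {
  e <- drop(as.matrix(x) %*% w) + b - y
  sum(w^2) / 2 + C * sum(pmax(0, abs(e) - epsilon)) +
    penalty$beta / 2 * psi(e, penalty)
}

#' @export
print.obsvr <- function(x, ...) {
  cat("Optimism-bias regularized SVR (", x$kernel, " kernel)\n", sep = "")
  cat(sprintf("  C = %g, epsilon = %g, beta = %g (%s side)\n",
              x$C, x$epsilon, x$penalty$beta, x$penalty$direction))
  cat(sprintf("  n = %d, final cost = %.6g, converged: %s\n",
              x$n, x$final_cost, x$converged))
  invisible(x)
}

#' @export
predict.obsvr <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  X <- as.matrix(newdata)
  if (ncol(X) != object$d)
    stop("newdata has ", ncol(X), " columns; model expects ", object$d)
  if (object$kernel == "linear") {
    drop(X %*% object$w) + object$b
  } else {
    drop(rbf_gram(X, object$x_train, object$gamma) %*% object$alpha) +
      object$b
  }
}

#' @export
coef.obsvr <- function(object, ...) {
  if (object$kernel == "linear") c("(Intercept)" = object$b, object$w)
  else c("(Intercept)" = object$b, alpha = object$alpha)
}

#' @export
residuals.obsvr <- function(object, type = c("prediction", "response"),
                            ...) {
  type <- match.arg(type)
  if (type == "prediction") object$residuals else -object$residuals
}

#' @export
fitted.obsvr <- function(object, ...) object$fitted.values
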