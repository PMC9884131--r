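#' Optimism-bias penalty configuration
#'
#' Builds the configuration of the one-sided penalty
#' \deqn{\Psi(e) = \sum_i (\pm\mathrm{sgn}(e_i) + 1)\,|e_i|^p}
#' on the signed residuals \eqn{e_i = h(X_i) - y_i} of a regression model.
#' With \code{direction = "over"} the sign factor is \eqn{\mathrm{sgn}(e_i)+1},
#' so only over-predictions (\eqn{e_i > 0}) are penalized; with
#' \code{direction = "under"} it is \eqn{-\mathrm{sgn}(e_i)+1} and only
#' under-predictions contribute. The penalty enters an objective as
#' \eqn{(\beta/2)\Psi}; it is convex for \eqn{\beta \ge 0}, \eqn{p \ge 1}
#' and strictly convex in the residuals on the penalized side for
#' \eqn{p > 1}.
#'
#' @param direction which side of the residual distribution to penalize:
#'   \code{"over"} (predictions above the target) or \code{"under"}.
#' @param p exponent of the \eqn{\ell_p} term, a single number \eqn{\ge 1}.
#'   The default 2 gives a one-sided squared penalty.
#' @param beta penalty weight \eqn{\beta \ge 0}; \code{beta = 0} disables
#'   the penalty.
#' @param normalization \code{"mean"} divides \eqn{\Psi} by the number of
#'   residuals so that \code{beta} is comparable across sample sizes;
#'   \code{"sum"} leaves the raw sum.
#' @return An object of class \code{"bias_penalty"}: a list with the four
#'   validated fields.
#' @examples
#' pen <- bias_penalty("over", beta = 1)
#' psi(c(1, -1), pen)
#' @seealso [psi()], [psi_gradient()], [total_cost()], [oblm()]
#' @export
bias_penalty <- function(direction = c("over", "under"), p = 2, beta = 0,
                         normalization = c("mean", "sum")) {
  direction <- match.arg(direction)
  normalization <- match.arg(normalization)
  stopifnot(is.numeric(p), length(p) == 1L, is.finite(p),
            is.numeric(beta), length(beta) == 1L, is.finite(beta))
  if (p < 1)
    stop("'p' must be >= 1 (convexity of the |e|^p term)")
  if (beta < 0)
    stop("'beta' must be >= 0")
  structure(list(direction = direction, p = p, beta = beta,
                 normalization = normalization),
            class = "bias_penalty")
}

#' @export
print.bias_penalty <- function(x, ...) {
  cat(sprintf(
    "Optimism-bias penalty: direction=%s, p=%g, beta=%g, normalization=%s\n",
    x$direction, x$p, x$beta, x$normalization))
  invisible(x)
}

stopifnot_penalty <- function(penalty) {
  if (!inherits(penalty, "bias_penalty"))
    stop("'penalty' must be created with bias_penalty()")
  invisible(penalty)
}

check_residuals <- function(e) {
  if (!is.numeric(e) || length(e) < 1L)
    stop("residuals must be a numeric vector of length >= 1")
  if (!all(is.finite(e)))
    stop("residuals must be finite")
  as.numeric(e)
}

#' Signed residuals of a prediction
#'
#' Computes \eqn{e_i = \hat y_i - y_i}. The sign convention is fixed
#' throughout the package: a positive residual is an over-prediction.
#'
#' @param predictions,targets numeric vectors of equal length.
#' @return Numeric vector of signed residuals, in input order.
#' @examples
#' signed_residuals(c(2, 1), c(1, 2))
#' @export
signed_residuals <- function(predictions, targets) {
  if (length(predictions) != length(targets))
    stop("'predictions' and 'targets' must have equal length")
  if (length(predictions) < 1L)
    stop("need at least one prediction")
  if (!all(is.finite(predictions)) || !all(is.finite(targets)))
    stop("inputs must be finite")
  as.numeric(predictions) - as.numeric(targets)
}

# sign factor of the penalty summand; sgn(0) = 0 so exact hits contribute 0
side_factor <- function(e, direction) {
  if (direction == "over") sign(e) + 1 else -sign(e) + 1
}

#' Optimism-bias penalty value
#'
#' Evaluates \eqn{\Psi(e) = \sum_i s_i |e_i|^p} where \eqn{s_i} is
#' \eqn{\mathrm{sgn}(e_i)+1} for \code{direction = "over"} and
#' \eqn{-\mathrm{sgn}(e_i)+1} for \code{"under"} (so the factor is 2 on the
#' penalized side, 0 on the other, and 0 at an exact hit). Under
#' \code{normalization = "mean"} the sum is divided by \code{length(e)}.
#'
#' @param residuals numeric vector of signed residuals
#'   (see [signed_residuals()]).
#' @param penalty a [bias_penalty()] object.
#' @return A single non-negative number; 0 exactly when no residual lies
#'   strictly on the penalized side.
#' @examples
#' psi(c(1, -1), bias_penalty("over", normalization = "sum"))  # 2
#' @export
psi <- function(residuals, penalty) {
  stopifnot_penalty(penalty)
  e <- check_residuals(residuals)
  v <- sum(side_factor(e, penalty$direction) * abs(e)^penalty$p)
  if (penalty$normalization == "mean") v / length(e) else v
}

#' Gradient of the optimism-bias penalty in residual space
#'
#' Element-wise derivative of the \eqn{\Psi} summand with respect to each
#' residual: \eqn{s_i \, p \, |e_i|^{p-1} \mathrm{sgn}(e_i)}, which is zero
#' on the unpenalized side and (by the subgradient choice) zero at
#' \eqn{e_i = 0}. For \eqn{p = 1} this is a subgradient; for \eqn{p = 2}
#' the penalty is continuously differentiable and the gradient is exact
#' everywhere. Scaled by \code{1/length(e)} under mean normalization.
#'
#' @inheritParams psi
#' @return Numeric vector, same length as \code{residuals}.
#' @examples
#' psi_gradient(1, bias_penalty("over", normalization = "sum"))  # 4
#' @export
psi_gradient <- function(residuals, penalty) {
  stopifnot_penalty(penalty)
  e <- check_residuals(residuals)
  g <- side_factor(e, penalty$direction) * penalty$p *
    abs(e)^(penalty$p - 1) * sign(e)
  g[e == 0] <- 0  # chosen subgradient; also kills 0^0 = 1 at p = 1
  if (penalty$normalization == "mean") g / length(e) else g
}

#' Regularized objective value
#'
#' Adds the weighted penalty to a base loss:
#' \code{base_loss + (beta/2) * psi(residuals, penalty)}. Equals
#' \code{base_loss} exactly when \code{beta = 0}.
#'
#' @param base_loss single finite number, typically a mean training loss.
#' @inheritParams psi
#' @return A single number.
#' @export
total_cost <- function(base_loss, residuals, penalty) {
  stopifnot(is.numeric(base_loss), length(base_loss) == 1L,
            is.finite(base_loss))
  base_loss + penalty$beta / 2 * psi(residuals, penalty)
}

#' Midpoint convexity check
#'
#' Numerically verifies the midpoint convexity inequality
#' \eqn{f((a+b)/2) \le (f(a)+f(b))/2} for a cost function along one
#' segment, up to an absolute tolerance that absorbs floating-point noise
#' on well-scaled costs.
#'
#' @param cost_at function mapping a parameter vector to a single finite
#'   cost value.
#' @param a,b parameter vectors of equal length (segment endpoints).
#' @param tol absolute slack added to the right-hand side.
#' @return \code{TRUE} if the inequality holds, \code{FALSE} otherwise.
#' @examples
#' check_midpoint_convexity(function(w) w^2, -1, 1)   # TRUE
#' check_midpoint_convexity(function(w) -w^2, -1, 1)  # FALSE
#' @export
check_midpoint_convexity <- function(cost_at, a, b, tol = 1e-9) {
  stopifnot(length(a) == length(b))
  fa <- cost_at(a)
  fb <- cost_at(b)
  fm <- cost_at((a + b) / 2)
  if (!all(is.finite(c(fa, fb, fm))))
    stop("cost function returned a non-finite value on the segment")
  fm <= (fa + fb) / 2 + tol
}
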