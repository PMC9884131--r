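#' Differentiable loss plug-in for externally trained models
#'
#' Packages the optimism-bias regularized mean squared error,
#' \eqn{\mathrm{MSE}(\hat y, y) + (\beta/2)\Psi(\hat y - y)}, as a pair of
#' functions of the predictions, suitable as a custom training loss for
#' any gradient-trained model (e.g. a neural sequence model) outside this
#' package.
#'
#' @param penalty a [bias_penalty()] object.
#' @return A list of class \code{"loss_plugin"} with elements
#'   \describe{
#'     \item{\code{value(predictions, targets)}}{the scalar loss.}
#'     \item{\code{gradient(predictions, targets)}}{its exact gradient
#'       with respect to the predictions, same length as the inputs.}
#'   }
#'   The two are mutually consistent: the gradient matches central finite
#'   differences of the value.
#' @examples
#' plug <- make_loss_plugin(bias_penalty("under", beta = 0.5))
#' plug$value(c(1, 2), c(2, 2))
#' plug$gradient(c(1, 2), c(2, 2))
#' @export
make_loss_plugin <- function(penalty = bias_penalty()) {
  stopifnot_penalty(penalty)
  structure(list(
    penalty = penalty,
    value = function(predictions, targets) {
      e <- signed_residuals(predictions, targets)
      mean(e^2) + penalty$beta / 2 * psi(e, penalty)
    },
    gradient = function(predictions, targets) {
      e <- signed_residuals(predictions, targets)
      2 * e / length(e) + penalty$beta / 2 * psi_gradient(e, penalty)
    }
  ), class = "loss_plugin")
}
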