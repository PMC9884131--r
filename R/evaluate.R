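#' Asymmetric evaluation of regression predictions
#'
#' Computes the usual squared-error summaries together with their
#' side-resolved versions on the signed residuals
#' \eqn{e = \hat y - y} (positive = over-prediction):
#' mean squared error, mean squared positive error (MSPE, over residuals
#' \eqn{e > 0}), mean squared negative error (MSNE, over \eqn{e < 0}),
#' the coefficient of determination \eqn{r^2}, and the counts and rates of
#' over-, under- and exactly-predicted instances. An empty side reports a
#' squared error of 0 with a count of 0, so that
#' \eqn{n\,\mathrm{MSE} = n_{over}\mathrm{MSPE} + n_{under}\mathrm{MSNE}}
#' holds exactly.
#'
#' @param y_true,y_pred numeric vectors of equal length.
#' @return An object of class \code{"eval_report"}: a list with fields
#'   \code{mse}, \code{mspe}, \code{msne}, \code{r2}, \code{r2_defined},
#'   \code{n}, \code{n_over}, \code{n_under}, \code{n_exact},
#'   \code{over_rate}, \code{under_rate}. When the target has zero
#'   variance, \code{r2} is \code{NA} and \code{r2_defined} is
#'   \code{FALSE} rather than an error.
#' @examples
#' evaluate_predictions(c(0, 0, 0, 0), c(1, 2, -1, 0))
#' @export
evaluate_predictions <- function(y_true, y_pred) {
  e <- signed_residuals(y_pred, y_true)
  n <- length(e)
  over <- e > 0
  under <- e < 0
  n_over <- sum(over)
  n_under <- sum(under)
  sst <- sum((y_true - mean(y_true))^2)
  r2_defined <- sst > 0
  structure(list(
    mse = mean(e^2),
    mspe = if (n_over > 0) mean(e[over]^2) else 0,
    msne = if (n_under > 0) mean(e[under]^2) else 0,
    r2 = if (r2_defined) 1 - sum(e^2) / sst else NA_real_,
    r2_defined = r2_defined,
    n = n, n_over = n_over, n_under = n_under,
    n_exact = n - n_over - n_under,
    over_rate = n_over / n,
    under_rate = n_under / n
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("mse = %.6g (mspe = %.6g on %d over, msne = %.6g on %d under)\n",
              x$mse, x$mspe, x$n_over, x$msne, x$n_under))
  cat(sprintf("r2 = %s, over_rate = %.3f, under_rate = %.3f, n = %d\n",
              if (x$r2_defined) sprintf("%.4f", x$r2) else "undefined",
              x$over_rate, x$under_rate, x$n))
  invisible(x)
}

#' @export
as.data.frame.eval_report <- function(x, ...) {
  data.frame(mse = x$mse, mspe = x$mspe, msne = x$msne, r2 = x$r2,
             n = x$n, n_over = x$n_over, n_under = x$n_under,
             n_exact = x$n_exact, over_rate = x$over_rate,
             under_rate = x$under_rate)
}

#' Count strictly under-predicted time points
#'
#' The number of indices where the prediction falls strictly below the
#' observed count — the day-level summary used to judge surge readiness of
#' a case-count forecaster.
#'
#' @param y_true,y_pred numeric vectors of equal length.
#' @return Integer count of indices with \code{y_pred < y_true}.
#' @export
count_underpredicted_days <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("'y_true' and 'y_pred' must have equal length")
  sum(y_pred < y_true)
}

#' Bias-variance estimation by replicated refits
#'
#' Estimates squared bias and variance of a fitting procedure by training
#' it on \code{n_replicates} independently generated datasets and
#' examining its predictions on a fixed test grid. At each grid point the
#' across-replicate variance of predictions and the squared difference
#' between the mean prediction and the true noiseless response are
#' computed; both are averaged over the grid.
#'
#' @param generator function of one argument (an integer seed) returning a
#'   list with elements \code{X} (matrix) and \code{y} (vector), e.g. a
#'   wrapper around [gen_linear()].
#' @param fitter function \code{(X, y)} returning any object supporting
#'   \code{predict(object, newdata)}.
#' @param n_replicates number of replicate datasets (>= 2).
#' @param test_grid feature matrix on which bias/variance are measured.
#' @param truth function mapping \code{test_grid} to the true noiseless
#'   response.
#' @param seed master seed; replicate seeds are drawn deterministically
#'   from it, so results do not depend on replicate ordering.
#' @return An object of class \code{"bias_variance"}: list with
#'   \code{bias_squared}, \code{variance}, \code{mean_r2} (training-set
#'   r2, averaged), \code{n_replicates}, and per-replicate /
#'   per-grid-point detail (\code{r2}, \code{pointwise_bias_squared},
#'   \code{pointwise_variance}, \code{predictions}).
#' @examples
#' gen <- function(s) gen_linear(200, 1, 2, 1, noise_sd = 0.5, seed = s)
#' bv <- bias_variance_estimate(gen, function(X, y) oblm(X, y),
#'                              n_replicates = 20,
#'                              test_grid = matrix(seq(0, 1, length = 50)),
#'                              truth = function(g) 2 * g[, 1] + 1,
#'                              seed = 1)
#' bv$bias_squared
#' @export
bias_variance_estimate <- function(generator, fitter, n_replicates,
                                   test_grid, truth, seed) {
  stopifnot(n_replicates >= 2)
  test_grid <- as.matrix(test_grid)
  rep_seeds <- replicate_seeds(seed, n_replicates)
  true_y <- truth(test_grid)
  stopifnot(length(true_y) == nrow(test_grid))

  preds <- matrix(NA_real_, nrow(test_grid), n_replicates)
  r2 <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    d <- generator(rep_seeds[r])
    fit <- tryCatch(fitter(d$X, d$y), error = function(err)
      stop("replicate ", r, " (seed ", rep_seeds[r], ") failed: ",
           conditionMessage(err)))
    preds[, r] <- predict(fit, test_grid)
    r2[r] <- evaluate_predictions(d$y, predict(fit, d$X))$r2
  }
  mean_pred <- rowMeans(preds)
  pt_var <- apply(preds, 1, stats::var)
  pt_bias2 <- (mean_pred - true_y)^2
  structure(list(
    bias_squared = mean(pt_bias2),
    variance = mean(pt_var),
    mean_r2 = mean(r2),
    n_replicates = n_replicates,
    r2 = r2,
    pointwise_bias_squared = pt_bias2,
    pointwise_variance = pt_var,
    predictions = preds,
    seed = seed
  ), class = "bias_variance")
}

#' @export
print.bias_variance <- function(x, ...) {
  cat(sprintf(
    "bias^2 = %.6g, variance = %.6g, mean r2 = %.4f (%d replicates)\n",
    x$bias_squared, x$variance, x$mean_r2, x$n_replicates))
  invisible(x)
}

# deterministic per-replicate seeds from one master seed, independent of
# any other use of the RNG and of grid position
replicate_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Serialize an evaluation report to JSON
#'
#' @param report an [evaluate_predictions()] result.
#' @param path optional file path; if \code{NULL} the JSON string is
#'   returned.
#' @export
write_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "eval_report"))
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
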