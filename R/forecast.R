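#' Sliding lag windows over a count series
#'
#' Turns a univariate series into a supervised matrix: row \eqn{i} holds
#' the \code{window_size} consecutive counts starting at day \eqn{i}, and
#' its target is the count \code{horizon} steps after the window ends.
#' Every feature timestamp strictly precedes its target timestamp, so no
#' future information leaks into the features.
#'
#' @param series a \code{surge_series} (or list with \code{counts}).
#' @param window_size number of lags per row.
#' @param horizon steps ahead of the window end to forecast (default 1).
#' @return A list of class \code{"windowed_series"}: \code{X}
#'   (n_windows x window_size), \code{y}, \code{target_day} (index of
#'   each target in the original series), \code{window_size},
#'   \code{horizon}. \code{n_windows = length - window_size - horizon
#'   + 1}.
#' @examples
#' w <- make_windows(list(counts = c(1, 2, 3, 4)), window_size = 2)
#' w$X; w$y
#' @export
make_windows <- function(series, window_size, horizon = 1) {
  counts <- as.numeric(series$counts)
  L <- length(counts)
  stopifnot(window_size >= 1, horizon >= 1)
  nw <- L - window_size - horizon + 1L
  if (nw < 1L)
    stop("series too short: need length > window_size + horizon - 1")
  X <- matrix(NA_real_, nw, window_size,
              dimnames = list(NULL, paste0("lag", window_size:1)))
  for (i in seq_len(nw))
    X[i, ] <- counts[i:(i + window_size - 1L)]
  target_day <- window_size + horizon - 1L + seq_len(nw)
  structure(list(X = X, y = counts[target_day], target_day = target_day,
                 window_size = window_size, horizon = horizon),
            class = "windowed_series")
}

#' Fit an autoregressive forecaster with an optimism-bias penalty
#'
#' Delegates to [oblm()] on the lag matrix of a windowed series. With
#' \code{direction = "under"} the penalty discourages forecasts below the
#' realized counts — the surge-readiness setting.
#'
#' @param train a [make_windows()] result.
#' @param penalty a [bias_penalty()] object.
#' @param ... further arguments to [oblm()] (\code{lambda2},
#'   \code{lambda1}, \code{tol}, \code{maxit}).
#' @return An \code{"oblm"} fit.
#' @export
fit_forecaster <- function(train, penalty = bias_penalty("under"), ...) {
  stopifnot(inherits(train, "windowed_series"))
  oblm(train$X, train$y, penalty = penalty, ...)
}

#' Train/test rolling evaluation of a surge forecaster
#'
#' Fits the windowed forecaster on the first \code{split} fraction of
#' windows and predicts one step ahead over the remaining windows without
#' refitting, then reports asymmetric error metrics and the strict
#' under-predicted-day count on the held-out span.
#'
#' @param series a \code{surge_series} (or list with \code{counts}).
#' @param window_size lag window length (default 14 days).
#' @param penalty a [bias_penalty()] object.
#' @param split fraction of windows used for training, in (0, 1).
#' @param horizon forecast horizon (default 1).
#' @param ... further arguments to [oblm()].
#' @return A list of class \code{"rolling_eval"}: \code{report} (an
#'   [evaluate_predictions()] result on the test span),
#'   \code{underpredicted_days}, \code{train_report},
#'   \code{train_underpredicted_days}, \code{model}, and
#'   \code{predictions} (data frame day/actual/predicted/residual over the
#'   test span).
#' @examples
#' s <- gen_surge_series(length = 200, surges = list(c(150, 400, 20)),
#'                       seed = 1)
#' r0 <- rolling_evaluate(s, penalty = bias_penalty("under", beta = 0))
#' r1 <- rolling_evaluate(s, penalty = bias_penalty("under", beta = 1))
#' c(r0$underpredicted_days, r1$underpredicted_days)
#' @export
rolling_evaluate <- function(series, window_size = 14,
                             penalty = bias_penalty("under"),
                             split = 0.7, horizon = 1, ...) {
  stopifnot(split > 0, split < 1)
  w <- make_windows(series, window_size, horizon)
  n_train <- floor(split * nrow(w$X))
  if (n_train < 1L || n_train >= nrow(w$X))
    stop("insufficient data on one side of the split")
  tr <- seq_len(n_train)
  model <- oblm(w$X[tr, , drop = FALSE], w$y[tr], penalty = penalty, ...)
  pred_test <- predict(model, w$X[-tr, , drop = FALSE])
  y_test <- w$y[-tr]
  pred_train <- predict(model, w$X[tr, , drop = FALSE])
  structure(list(
    report = evaluate_predictions(y_test, pred_test),
    underpredicted_days = count_underpredicted_days(y_test, pred_test),
    train_report = evaluate_predictions(w$y[tr], pred_train),
    train_underpredicted_days = count_underpredicted_days(w$y[tr],
                                                          pred_train),
    model = model,
    predictions = data.frame(day = w$target_day[-tr], actual = y_test,
                             predicted = pred_test,
                             residual = pred_test - y_test),
    window_size = window_size, horizon = horizon, split = split
  ), class = "rolling_eval")
}

#' @export
print.rolling_eval <- function(x, ...) {
  cat(sprintf(
    "Rolling forecast evaluation (window %d, split %.2f, beta = %g, %s)\n",
    x$window_size, x$split, x$model$penalty$beta,
    x$model$penalty$direction))
  cat(sprintf("Test span: %d days, under-predicted on %d\n",
              x$report$n, x$underpredicted_days))
  print(x$report)
  invisible(x)
}

#' Write per-day forecast predictions to CSV
#'
#' Columns \code{day,actual,predicted,residual}, fixed numeric formatting.
#'
#' @param result a [rolling_evaluate()] result.
#' @param path file path.
#' @export
write_predictions_csv <- function(result, path) {
  stopifnot(inherits(result, "rolling_eval"))
  utils::write.csv(format_numeric_df(result$predictions), path,
                   row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
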