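#' Save and load fitted models as JSON
#'
#' Serializes an [oblm()] or [obsvr()] fit — coefficients, intercept, the
#' penalty and solver configuration, and convergence diagnostics — to a
#' plain-text JSON file. The loaded object supports \code{predict()} and
#' \code{coef()}.
#'
#' @param model an \code{"oblm"} or \code{"obsvr"} object.
#' @param path file path.
#' @return \code{write_model_json} invisibly returns \code{path};
#'   \code{read_model_json} returns the reconstructed model object.
#' @examples
#' d <- gen_linear(50, 1, 2, 1, noise_sd = 0.1, seed = 1)
#' fit <- oblm(d$X, d$y)
#' f <- tempfile(fileext = ".json")
#' write_model_json(fit, f)
#' all.equal(coef(read_model_json(f)), coef(fit))
#' @export
write_model_json <- function(model, path) {
  pen <- model$penalty
  common <- list(
    penalty = unclass(pen),
    converged = model$converged,
    n_iterations = model$n_iterations,
    final_cost = model$final_cost,
    n = model$n, d = model$d
  )
  payload <- if (inherits(model, "oblm")) {
    c(list(type = "oblm", W = as.numeric(model$W),
           feature_names = names(model$W), b = model$b,
           lambda2 = model$lambda2, lambda1 = model$lambda1,
           tol = model$tol, maxit = model$maxit), common)
  } else if (inherits(model, "obsvr")) {
    extra <- if (model$kernel == "linear") {
      list(w = as.numeric(model$w), feature_names = names(model$w))
    } else {
      list(alpha = as.numeric(model$alpha), gamma = model$gamma,
           x_train = model$x_train)
    }
    c(list(type = "obsvr", kernel = model$kernel, b = model$b,
           C = model$C, epsilon = model$epsilon), extra, common)
  } else stop("unsupported model class")
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                              matrix = "rowmajor"), path)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  p <- jsonlite::fromJSON(path)
  pen <- bias_penalty(p$penalty$direction, p$penalty$p, p$penalty$beta,
                      p$penalty$normalization)
  if (identical(p$type, "oblm")) {
    W <- stats::setNames(as.numeric(p$W), p$feature_names)
    structure(list(W = W, b = p$b,
                   coefficients = c("(Intercept)" = p$b, W),
                   converged = p$converged,
                   n_iterations = p$n_iterations,
                   final_cost = p$final_cost, penalty = pen,
                   lambda2 = p$lambda2, lambda1 = p$lambda1,
                   tol = p$tol, maxit = p$maxit, n = p$n, d = p$d),
              class = "oblm")
  } else if (identical(p$type, "obsvr")) {
    out <- list(b = p$b, kernel = p$kernel, C = p$C,
                epsilon = p$epsilon, penalty = pen,
                converged = p$converged, n_iterations = p$n_iterations,
                final_cost = p$final_cost, n = p$n, d = p$d)
    if (p$kernel == "linear") {
      out$w <- stats::setNames(as.numeric(p$w), p$feature_names)
    } else {
      out$alpha <- as.numeric(p$alpha)
      out$gamma <- p$gamma
      out$x_train <- as.matrix(p$x_train)
    }
    structure(out, class = "obsvr")
  } else stop("unrecognized model JSON at ", path)
}
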