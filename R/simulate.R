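#' @name synthetic-data
#' @title Seeded synthetic data generators
#' @description
#' Three generators emulate the data regimes on which one-sided penalties
#' are typically studied: linear regression data with Gaussian noise,
#' epidemic daily-case curves with baseline/surge/decay phases, and
#' monotone degradation trajectories with a run-to-failure endpoint and
#' remaining-useful-life (RUL) targets. All are pure functions of their
#' arguments including the seed, and carry a \code{truth} record from
#' which the noiseless response can be regenerated exactly.
NULL

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Linear regression data with Gaussian noise
#'
#' Draws \code{X} i.i.d. uniform on \eqn{[0,1]^d} and
#' \code{y = X coefficients + intercept + N(0, noise_sd^2)}.
#'
#' @param n number of instances.
#' @param d number of features; must equal \code{length(coefficients)}.
#' @param coefficients true coefficient vector.
#' @param intercept true intercept.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed integer seed; identical seeds give identical datasets.
#' @return A list of class \code{"synth_dataset"}: \code{X} (n x d
#'   matrix), \code{y}, and \code{truth} (coefficients, intercept,
#'   noise_sd).
#' @examples
#' d <- gen_linear(100, 1, 2, 1, noise_sd = 0, seed = 1)
#' all.equal(d$y, drop(d$X %*% 2) + 1)
#' @rdname synthetic-data
#' @export
gen_linear <- function(n, d, coefficients, intercept = 0, noise_sd = 0.5,
                       seed = 1) {
  stopifnot(n >= 1, d >= 1, length(coefficients) == d, noise_sd >= 0)
  with_seed(seed, {
    X <- matrix(stats::runif(n * d), n, d,
                dimnames = list(NULL, paste0("x", seq_len(d))))
    y <- drop(X %*% coefficients) + intercept +
      stats::rnorm(n, 0, noise_sd)
    structure(list(X = X, y = y,
                   truth = list(coefficients = coefficients,
                                intercept = intercept,
                                noise_sd = noise_sd),
                   seed = seed),
              class = "synth_dataset")
  })
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat(sprintf("Synthetic linear dataset: n = %d, d = %d, noise_sd = %g\n",
              nrow(x$X), ncol(x$X), x$truth$noise_sd))
  invisible(x)
}

#' Epidemic-style surge time series
#'
#' Builds a latent daily-incidence curve as a constant baseline plus
#' Gaussian-shaped surges, adds observation noise, and floors at zero:
#' \code{counts = max(0, latent + N(0, noise_sd^2))}. A stand-in for a
#' daily positive-case curve with distinct baseline, surge and decay
#' phases.
#'
#' @param length number of days (>= 30).
#' @param baseline constant latent level between surges.
#' @param surges list of surge descriptors \code{c(peak_day, peak_height,
#'   width)}; peaks must lie inside \code{[1, length]}.
#' @param noise_sd observation noise standard deviation.
#' @param seed integer seed.
#' @return A list of class \code{"surge_series"}: \code{day} (1..length),
#'   \code{counts} (non-negative), and \code{truth} with the latent curve
#'   and the generating parameters.
#' @rdname synthetic-data
#' @export
gen_surge_series <- function(length = 534, baseline = 50,
                             surges = list(c(150, 400, 20),
                                           c(380, 900, 25)),
                             noise_sd = 30, seed = 1) {
  stopifnot(length >= 30, baseline >= 0, noise_sd >= 0)
  day <- seq_len(length)
  latent <- rep(baseline, length)
  for (s in surges) {
    if (base::length(s) != 3)
      stop("each surge must be c(peak_day, peak_height, width)")
    if (s[1] < 1 || s[1] > length)
      stop("surge peak day ", s[1], " outside the series range")
    latent <- latent + s[2] * exp(-0.5 * ((day - s[1]) / s[3])^2)
  }
  with_seed(seed, {
    counts <- pmax(0, latent + stats::rnorm(length, 0, noise_sd))
    structure(list(day = day, counts = counts,
                   truth = list(latent = latent, baseline = baseline,
                                surges = surges, noise_sd = noise_sd),
                   seed = seed),
              class = "surge_series")
  })
}

#' @export
print.surge_series <- function(x, ...) {
  cat(sprintf(
    "Synthetic surge series: %d days, baseline %g, %d surge(s), peak count %g\n",
    length(x$day), x$truth$baseline, length(x$truth$surges),
    max(x$counts)))
  invisible(x)
}

#' Run-to-failure degradation data with RUL targets
#'
#' Each of \code{n_units} units gets a lifetime drawn uniformly (in whole
#' cycles) from \code{cycles_range}; the target at cycle \eqn{t} is the
#' remaining useful life \eqn{RUL = lifetime - t} (linear degradation, no
#' capping plateau). Sensor channels read the underlying health state
#' linearly: \code{reading = offset_k + slope_uk * RUL + N(0,
#' noise_sd^2)}, with per-unit slope heterogeneity
#' \code{slope_uk = slope_k * (1 + heterogeneity * u)},
#' \code{u ~ U(-1, 1)}. With \code{noise_sd = 0} and
#' \code{heterogeneity = 0} the RUL is exactly linearly decodable from
#' any single sensor.
#'
#' @param n_units number of units (engines).
#' @param cycles_range integer pair (min, max) lifetime, min >= 1.
#' @param n_sensors number of sensor channels.
#' @param noise_sd sensor noise standard deviation.
#' @param heterogeneity relative spread of per-unit sensor slopes
#'   (0 = identical degradation law across units).
#' @param seed integer seed.
#' @return A list of class \code{"degradation_data"}: \code{X} (sensor
#'   readings, one row per unit-cycle), \code{y} (RUL), \code{unit},
#'   \code{cycle}, and \code{truth} (lifetimes, sensor offsets/slopes).
#' @rdname synthetic-data
#' @export
gen_degradation <- function(n_units = 20, cycles_range = c(128, 362),
                            n_sensors = 3, noise_sd = 5,
                            heterogeneity = 0.2, seed = 1) {
  stopifnot(n_units >= 1, length(cycles_range) == 2,
            cycles_range[1] >= 1, cycles_range[2] >= cycles_range[1],
            n_sensors >= 1, noise_sd >= 0, heterogeneity >= 0)
  with_seed(seed, {
    lifetimes <- floor(stats::runif(n_units, cycles_range[1],
                                    cycles_range[2] + 1))
    lifetimes <- pmin(lifetimes, cycles_range[2])
    offsets <- stats::runif(n_sensors, -1, 1)
    slopes <- stats::runif(n_sensors, 0.5, 1.5)
    rows <- sum(lifetimes)
    X <- matrix(NA_real_, rows, n_sensors,
                dimnames = list(NULL, paste0("s", seq_len(n_sensors))))
    y <- numeric(rows)
    unit <- integer(rows)
    cycle <- integer(rows)
    at <- 0L
    unit_slopes <- matrix(NA_real_, n_units, n_sensors)
    for (u in seq_len(n_units)) {
      life <- lifetimes[u]
      t <- seq_len(life)
      rul <- life - t
      us <- slopes * (1 + heterogeneity * stats::runif(n_sensors, -1, 1))
      unit_slopes[u, ] <- us
      idx <- at + seq_len(life)
      for (k in seq_len(n_sensors)) {
        X[idx, k] <- offsets[k] + us[k] * rul +
          if (noise_sd > 0) stats::rnorm(life, 0, noise_sd) else 0
      }
      y[idx] <- rul
      unit[idx] <- u
      cycle[idx] <- t
      at <- at + life
    }
    structure(list(X = X, y = y, unit = unit, cycle = cycle,
                   truth = list(lifetimes = lifetimes, offsets = offsets,
                                slopes = slopes, unit_slopes = unit_slopes,
                                noise_sd = noise_sd,
                                heterogeneity = heterogeneity),
                   seed = seed),
              class = "degradation_data")
  })
}

#' @export
print.degradation_data <- function(x, ...) {
  cat(sprintf(
    "Synthetic degradation data: %d units, lifetimes %d-%d, %d sensors, %d rows\n",
    length(x$truth$lifetimes), min(x$truth$lifetimes),
    max(x$truth$lifetimes), ncol(x$X), nrow(x$X)))
  invisible(x)
}

#' Read and write synthetic datasets as CSV
#'
#' Datasets are written as feature columns plus a final \code{y} column;
#' time series as \code{day,count}. Comma separator, header row, UTF-8.
#'
#' @param dataset a \code{synth_dataset} (or any list with \code{X},
#'   \code{y}).
#' @param path file path.
#' @return \code{read_dataset_csv} returns a list with \code{X} and
#'   \code{y}; \code{read_series_csv} a list with \code{day} and
#'   \code{counts}.
#' @export
write_dataset_csv <- function(dataset, path) {
  df <- as.data.frame(dataset$X)
  df$y <- dataset$y
  utils::write.csv(format_numeric_df(df), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  if (!"y" %in% names(df)) stop("no 'y' column in ", path)
  list(X = as.matrix(df[setdiff(names(df), "y")]), y = df$y)
}

#' @rdname write_dataset_csv
#' @param series a \code{surge_series} (or any list with \code{day},
#'   \code{counts}).
#' @export
write_series_csv <- function(series, path) {
  df <- data.frame(day = series$day, count = series$counts)
  utils::write.csv(format_numeric_df(df), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  if (!all(c("day", "count") %in% names(df)))
    stop("expected 'day,count' columns in ", path)
  list(day = df$day, counts = df$count)
}

# fixed 10-significant-digit formatting for byte-reproducible CSVs
format_numeric_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]]))
      df[[j]] <- formatC(df[[j]], digits = 10, format = "g")
  }
  df
}
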