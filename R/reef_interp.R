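#' Fit a spatial interpolator to percent-cover samples
#'
#' The package's central fitting function. The formula names the taxon and
#' declares the constant-mean model both interpolators assume
#' (`sponges ~ 1`); `data` is a `reef_samples` table. For ordinary kriging
#' the spatial structure is estimated here — empirical semivariogram, then
#' weighted-least-squares model fit — unless a pre-fitted
#' [variogram_model()] is supplied. The returned object predicts at new
#' locations or on grids, and its `summary`/`residuals` methods report
#' leave-one-out cross-validation accuracy (mean absolute error and
#' r-squared of predicted against measured).
#'
#' @param formula `taxon ~ 1`; the response names a cover column of `data`.
#' @param data a `reef_samples` data frame (see [read_samples()]).
#' @param method `"IDW"` or `"OK"`.
#' @param power IDW inverse-distance exponent.
#' @param variogram optional pre-fitted [variogram_model()] (OK only).
#' @param model_type variogram family to fit when none is supplied.
#' @param window a [search_window()]; by default a circle of radius twice
#'   the fitted range (OK) or 50 m (IDW), 3-15 neighbours.
#' @param lag_width,max_lag variography controls (OK).
#' @param clamp_to_range clamp grid predictions into `[0, 100]`.
#' @return An object of class `reef_interp` with `print`, `summary`,
#'   `coef`, `predict`, `fitted`, `residuals` and `plot` methods.
#' @examples
#' reef <- simulate_reef(seed = 7, grid = grid_spec(0, 0, 60, 40, 5),
#'                       design = transect_design(n_transects = 3,
#'                                                transect_spacing = 100))
#' fit <- reef_interp(sponges ~ 1, reef$samples, method = "IDW", power = 2)
#' fit
#' predict(fit, data.frame(x = c(50, 100), y = c(60, 100)))
#' @export
reef_interp <- function(formula, data, method = c("IDW", "OK"), power = 2,
                        variogram = NULL, model_type = "spherical",
                        window = NULL, lag_width = NULL, max_lag = 100,
                        clamp_to_range = TRUE) {
  method <- match.arg(toupper(method[1L]), c("IDW", "OK"))
  stopifnot(inherits(formula, "formula"))
  if (length(formula) != 3L)
    stop("formula must have the form taxon ~ 1")
  taxon <- all.vars(formula[[2L]])
  if (length(taxon) != 1L)
    stop("the formula response must name exactly one cover column")
  rhs <- formula[[3L]]
  if (!identical(rhs, 1) && !identical(rhs, quote(`1`)) &&
      !(is.numeric(rhs) && rhs == 1))
    stop("only the constant-mean model 'taxon ~ 1' is supported")
  z <- sample_cover(data, taxon)   # validates the column exists
  if (method == "OK" && is.null(variogram)) {
    emp <- empirical_variogram(data, taxon, lag_width = lag_width,
                               max_lag = max_lag)
    variogram <- fit_variogram(emp, model_type)
  }
  if (is.null(window)) {
    radius <- if (method == "OK") 2 * variogram$range else 50
    window <- search_window(2 * radius, 2 * radius)
  }
  config <- interp_config(method, power = power, variogram = variogram,
                          window = window, clamp_to_range = clamp_to_range)
  structure(list(call = match.call(), taxon = taxon, data = data,
                 config = config, n = length(z), cache = new.env()),
            class = "reef_interp")
}

#' @export
print.reef_interp <- function(x, ...) {
  cat(sprintf("reef_interp: %s of '%s' on %d samples\n", x$config$method,
              x$taxon, x$n))
  cat(" ", describe_config(x$config), "\n")
  invisible(x)
}

#' @export
coef.reef_interp <- function(object, ...) {
  if (object$config$method == "IDW") c(power = object$config$power)
  else coef(object$config$variogram)
}

cv_of <- function(object) {
  if (is.null(object$cache$cv))
    object$cache$cv <- loo_crossval(object$data, object$taxon, object$config)
  object$cache$cv
}

#' @export
summary.reef_interp <- function(object, ...) {
  cv <- cv_of(object)
  structure(list(fit = object, cv = cv), class = "summary.reef_interp")
}

#' @export
print.summary.reef_interp <- function(x, ...) {
  print(x$fit)
  cat("Leave-one-out cross-validation:\n")
  print(x$cv)
  invisible(x)
}

#' @export
fitted.reef_interp <- function(object, ...) cv_of(object)$pairs$predicted

#' @export
residuals.reef_interp <- function(object, ...) {
  p <- cv_of(object)$pairs
  p$predicted - p$measured
}

#' Predict from a fitted interpolator
#'
#' @param object a [reef_interp()] fit.
#' @param newdata a data frame with `x` and `y` columns, or a [grid_spec()]
#'   for a full raster prediction.
#' @param ... unused.
#' @return A numeric vector of predictions (with kriging variances in
#'   attribute `"variance"` for OK), or a [cover_raster()] when `newdata`
#'   is a grid.
#' @export
predict.reef_interp <- function(object, newdata, ...) {
  if (inherits(newdata, "grid_spec"))
    return(predict_grid(object$data, newdata, object$config, object$taxon))
  stopifnot(is.data.frame(newdata), all(c("x", "y") %in% names(newdata)))
  n <- nrow(newdata)
  pred <- numeric(n); pvar <- numeric(n)
  for (i in seq_len(n)) {
    loc <- c(newdata$x[i], newdata$y[i])
    if (object$config$method == "IDW") {
      pred[i] <- idw_predict(object$data, loc, object$config, object$taxon)
      pvar[i] <- NA_real_
    } else {
      pv <- ok_predict(object$data, loc, object$config, object$taxon)
      pred[i] <- pv[1L]; pvar[i] <- pv[2L]
    }
  }
  if (object$config$method == "OK") attr(pred, "variance") <- pvar
  pred
}

#' @export
plot.reef_interp <- function(x, grid = NULL, ...) {
  if (is.null(grid)) {
    span_x <- range(x$data$x); span_y <- range(x$data$y)
    cs <- max(1, round(max(diff(span_x), diff(span_y)) / 100))
    grid <- grid_spec(span_x[1L], span_y[1L],
                      max(1L, ceiling(diff(span_x) / cs)),
                      max(1L, ceiling(diff(span_y) / cs)), cs)
  }
  r <- predict(x, grid)
  plot(r, main = sprintf("%s (%s)", x$taxon, x$config$method), ...)
  invisible(r)
}
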