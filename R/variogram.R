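#' Parametric semivariogram model
#'
#' Describes spatial autocorrelation through a nugget / partial-sill / range
#' parameterisation. Supported families: `"nugget"`, `"spherical"`,
#' `"exponential"` and `"gaussian"`. For the exponential and gaussian
#' families `range` is the *effective* range — the distance at which the
#' semivariance reaches 95% of the partial sill above the nugget (the
#' convention used by common GIS geostatistics tools). Divide by 3 (or
#' sqrt(3)) to recover the classical exponential (gaussian) range parameter.
#'
#' @param model_type one of `"nugget"`, `"spherical"`, `"exponential"`,
#'   `"gaussian"`.
#' @param nugget nugget variance `c0 >= 0` (cover^2 units).
#' @param psill partial sill `c >= 0`; the total sill is `nugget + psill`.
#' @param range range `a > 0`, metres (ignored for pure nugget but must still
#'   be positive).
#' @return An object of class `variogram_model`.
#' @examples
#' m <- variogram_model("spherical", nugget = 0, psill = 2, range = 10)
#' model_gamma(m, c(0, 5, 10, 20))
#' @export
variogram_model <- function(model_type = c("spherical", "exponential",
                                           "gaussian", "nugget"),
                            nugget = 0, psill = 1, range = 1) {
  model_type <- match.arg(model_type)
  stopifnot(is.numeric(nugget), nugget >= 0, is.numeric(psill), psill >= 0,
            is.numeric(range), range > 0)
  structure(list(model_type = model_type, nugget = as.numeric(nugget),
                 psill = as.numeric(psill), range = as.numeric(range)),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("variogram_model: %s(nugget = %.4g, psill = %.4g, range = %.4g m)\n",
              x$model_type, x$nugget, x$psill, x$range))
  invisible(x)
}

#' @export
coef.variogram_model <- function(object, ...) {
  c(nugget = object$nugget, psill = object$psill, range = object$range)
}

#' Evaluate a semivariogram model
#'
#' Computes `gamma(h)` for the given model. `gamma(0) = 0` by convention for
#' every family (the nugget is a discontinuity at the origin).
#'
#' @param model a [variogram_model()].
#' @param h vector of non-negative lag distances, metres.
#' @return Semivariances, same length as `h`.
#' @export
model_gamma <- function(model, h) {
  stopifnot(inherits(model, "variogram_model"), is.numeric(h))
  if (any(h < 0)) stop("lag distances must be non-negative")
  c0 <- model$nugget; c1 <- model$psill; a <- model$range
  g <- switch(model$model_type,
    nugget = { out <- h; out[] <- c0 + c1; out },  # keep matrix shape
    spherical = {
      hr <- pmin(h / a, 1)
      c0 + c1 * (1.5 * hr - 0.5 * hr^3)
    },
    exponential = c0 + c1 * (1 - exp(-3 * h / a)),
    gaussian = c0 + c1 * (1 - exp(-3 * h^2 / a^2)))
  g[h == 0] <- 0
  g
}

#' @export
predict.variogram_model <- function(object, h, ...) model_gamma(object, h)

# Covariance implied by the model: C(h) = sill - gamma(h), with C(0) = sill.
model_cov <- function(model, h) {
  (model$nugget + model$psill) - model_gamma(model, h)
}

#' Empirical semivariogram (Matheron estimator)
#'
#' Bins unordered point pairs by separation distance and computes the
#' classical Matheron estimator
#' `gamma(h) = sum (z_i - z_j)^2 / (2 N(h))` per bin. Bin `k`
#' (`k = 1, 2, ...`) is centred at `k * lag_width` and collects pairs with
#' separation in `[(k - 0.5) * lag_width, (k + 0.5) * lag_width)`; pairs
#' closer than half a lag (but not coincident) join the first bin. Centred
#' bins report regular-design pair distances at their true lag instead of
#' shifting them by half a bin. Empty bins are kept (with `n_pairs = 0` and
#' `gamma = NA`) so that gaps in the pair distribution stay visible.
#'
#' @param samples a `reef_samples` data frame (see [read_samples()]) or any
#'   data frame with `x`, `y` and the taxon column.
#' @param taxon name of the cover column to use.
#' @param lag_width bin width, metres (> 0). Default: the smallest non-zero
#'   pair distance (the sampling spacing on a regular design).
#' @param max_lag largest separation considered, metres. Default: half the
#'   maximum pairwise distance.
#' @return An object of class `empirical_variogram`: a data frame with
#'   columns `lag`, `gamma`, `n_pairs` and attributes `taxon`, `lag_width`,
#'   `max_lag`, `n`.
#' @export
empirical_variogram <- function(samples, taxon, lag_width = NULL,
                                max_lag = NULL) {
  z <- sample_cover(samples, taxon)
  x <- samples$x; y <- samples$y
  n <- length(z)
  if (n < 2L) stop("need at least 2 samples for a variogram")
  d <- stats::dist(cbind(x, y))
  dz2 <- stats::dist(z)^2
  d <- as.numeric(d); dz2 <- as.numeric(dz2)
  if (is.null(lag_width)) {
    pos <- d[d > 0]
    if (length(pos) == 0L) stop("all points are coincident")
    lag_width <- min(pos)
  }
  if (is.null(max_lag)) max_lag <- max(d) / 2
  if (lag_width <= 0) stop("lag_width must be > 0")
  if (max_lag < lag_width) stop("max_lag must be >= lag_width")
  n_bins <- ceiling(max_lag / lag_width)
  keep <- d > 0 & d < (n_bins + 0.5) * lag_width
  bin <- pmax(1L, as.integer(floor(d[keep] / lag_width + 0.5)))
  npairs <- tabulate(bin, nbins = n_bins)
  if (sum(npairs) == 0L)
    stop("no point pairs fall within max_lag")
  ssq <- vapply(seq_len(n_bins), function(k) sum(dz2[keep][bin == k]),
                numeric(1))
  gamma <- ifelse(npairs > 0L, ssq / (2 * npairs), NA_real_)
  out <- data.frame(lag = seq_len(n_bins) * lag_width,
                    gamma = gamma, n_pairs = npairs)
  structure(out, class = c("empirical_variogram", "data.frame"),
            taxon = taxon, lag_width = lag_width, max_lag = max_lag, n = n)
}

#' @export
print.empirical_variogram <- function(x, ...) {
  cat(sprintf("empirical_variogram of '%s': %d bins (width %g m, max lag %g m), %d points\n",
              attr(x, "taxon"), nrow(x), attr(x, "lag_width"),
              attr(x, "max_lag"), attr(x, "n")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @export
plot.empirical_variogram <- function(x, model = NULL, ...) {
  ok <- x$n_pairs > 0
  graphics::plot(x$lag[ok], x$gamma[ok], xlab = "lag (m)",
                 ylab = expression(gamma(h)), pch = 16,
                 ylim = c(0, max(x$gamma[ok])), ...)
  if (!is.null(model)) {
    hh <- seq(0, max(x$lag), length.out = 200)
    graphics::lines(hh, model_gamma(model, hh), col = "steelblue", lwd = 2)
  }
  invisible(x)
}

#' Fit a semivariogram model by weighted least squares
#'
#' Minimises the Cressie-weighted sum of squares
#' `sum_k N(h_k) * (gamma_emp(h_k) - gamma_model(h_k))^2 / gamma_model(h_k)^2`
#' over `(nugget, psill, range)` subject to `nugget, psill >= 0` and
#' `0 < range <= 2 * max_lag`, using L-BFGS-B from three fixed starting
#' points (structure-dominated, half-nugget, long-range). The fit is
#' deterministic given the empirical variogram.
#'
#' @param emp an [empirical_variogram()].
#' @param model_type model family to fit (see [variogram_model()]).
#' @return A `variogram_fit` object (inherits `variogram_model`), with the
#'   attained objective in `$objective`, the empirical variogram in `$emp`
#'   and a `$degenerate` flag set when the fit collapses to a pure-nugget
#'   structure (psill ~ 0 or range at its bound).
#' @export
fit_variogram <- function(emp, model_type = c("spherical", "exponential",
                                              "gaussian", "nugget")) {
  model_type <- match.arg(model_type)
  stopifnot(inherits(emp, "empirical_variogram"))
  use <- emp$n_pairs > 0 & is.finite(emp$gamma)
  h <- emp$lag[use]; g <- emp$gamma[use]; w <- emp$n_pairs[use]
  if (length(h) < 3L) stop("need at least 3 non-empty lag bins to fit")
  max_lag <- attr(emp, "max_lag")

  if (all(g == 0)) {
    warning("all empirical semivariances are zero; returning a degenerate pure-nugget model")
    fit <- variogram_model("nugget", nugget = 0, psill = 0, range = max_lag)
    return(as_variogram_fit(fit, 0, emp, degenerate = TRUE))
  }

  if (model_type == "nugget") {
    # gamma(h > 0) = c0 + c is flat: only the total sill is identifiable.
    sill <- sum(w * g) / sum(w)
    fit <- variogram_model("nugget", nugget = sill, psill = 0, range = max_lag)
    obj <- sum(w * (g - sill)^2 / sill^2)
    return(as_variogram_fit(fit, obj, emp, degenerate = FALSE))
  }

  s2 <- max(g)
  objective <- function(par) {
    m <- variogram_model(model_type, nugget = par[1], psill = par[2],
                         range = par[3])
    gm <- model_gamma(m, h)
    gm <- pmax(gm, 1e-10 * s2)
    sum(w * (g - gm)^2 / gm^2)
  }
  starts <- list(c(1e-3 * s2, s2, max_lag / 2),
                 c(s2 / 2, s2 / 2, max_lag / 4),
                 c(0.1 * s2, 0.9 * s2, max_lag))
  lower <- c(0, 0, 1e-6 * max_lag)
  upper <- c(2 * s2, 4 * s2, 2 * max_lag)
  best <- NULL
  for (p0 in starts) {
    res <- tryCatch(
      stats::optim(p0, objective, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(factr = 1e4, maxit = 500,
                                  parscale = c(s2, s2, max_lag))),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) stop("variogram fit failed from every starting point")
  par <- best$par
  # no resolvable structure: vanished partial sill, range pinned at the
  # bound, or range collapsed below the first observed lag (the model is
  # then indistinguishable from pure nugget at every bin)
  degenerate <- par[2] <= 1e-8 * s2 ||
    par[3] >= 2 * max_lag * (1 - 1e-6) || par[3] <= min(h) / 2
  fit <- variogram_model(model_type, nugget = par[1], psill = par[2],
                         range = max(par[3], lower[3]))
  as_variogram_fit(fit, best$value, emp, degenerate = degenerate)
}

as_variogram_fit <- function(model, objective, emp, degenerate) {
  model$objective <- objective
  model$emp <- emp
  model$degenerate <- degenerate
  class(model) <- c("variogram_fit", "variogram_model")
  model
}

#' @export
print.variogram_fit <- function(x, ...) {
  NextMethod()
  cat(sprintf("  WLS objective %.4g over %d bins%s\n", x$objective,
              sum(x$emp$n_pairs > 0),
              if (isTRUE(x$degenerate)) " [degenerate: no resolvable spatial structure]" else ""))
  invisible(x)
}

#' @export
plot.variogram_fit <- function(x, ...) {
  plot(x$emp, model = x, ...)
}

#' Select the best-fitting variogram family by cross-validation
#'
#' Fits each candidate family to the empirical variogram of `taxon`, then
#' scores each fitted model by the mean absolute error of leave-one-out
#' ordinary-kriging cross-validation, mirroring the model-selection step of
#' a variography workflow. Ties on ME are broken by higher r-squared, then by
#' smaller nugget (the model using its structured component more).
#'
#' @param samples a `reef_samples` data frame.
#' @param taxon cover column to model.
#' @param candidates character vector of model families.
#' @param window [search_window()] used for the cross-validation kriging.
#' @param lag_width,max_lag passed to [empirical_variogram()].
#' @return The winning `variogram_fit`, with the per-candidate score table in
#'   attribute `"selection"`.
#' @export
select_best_model <- function(samples, taxon,
                              candidates = c("spherical", "exponential"),
                              window = search_window(100, 100),
                              lag_width = NULL, max_lag = NULL) {
  stopifnot(length(candidates) >= 1L)
  emp <- empirical_variogram(samples, taxon, lag_width = lag_width,
                             max_lag = max_lag)
  fits <- lapply(candidates, function(ct) fit_variogram(emp, ct))
  if (length(fits) == 1L) return(fits[[1L]])
  scores <- lapply(fits, function(f) {
    cfg <- interp_config("OK", variogram = f, window = window)
    rep <- loo_crossval(samples, taxon, cfg)
    c(ME = rep$ME, r2 = if (is.na(rep$r2)) -Inf else rep$r2,
      nugget = f$nugget)
  })
  tab <- data.frame(model_type = candidates,
                    ME = vapply(scores, `[[`, numeric(1), "ME"),
                    r2 = vapply(scores, `[[`, numeric(1), "r2"),
                    nugget = vapply(scores, `[[`, numeric(1), "nugget"))
  ord <- order(tab$ME, -tab$r2, tab$nugget)
  best <- fits[[ord[1L]]]
  attr(best, "selection") <- tab
  best
}
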