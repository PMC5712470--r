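#' Elliptical search neighbourhood
#'
#' Both interpolators draw their neighbours from an ellipse centred on the
#' prediction location: semi-axes `axis1 / 2` (major) and `axis2 / 2`
#' (minor), with the major axis oriented `bearing` degrees clockwise from
#' north. With `axis1 == axis2` the window is a circle of that diameter.
#'
#' @param axis1 full length of the major axis, metres.
#' @param axis2 full length of the minor axis, metres (`0 < axis2 <= axis1`).
#' @param bearing major-axis orientation, degrees clockwise from north.
#' @param min_neighbors minimum number of neighbours required for a
#'   prediction; locations with fewer get NODATA.
#' @param max_neighbors largest number of (nearest) neighbours used.
#' @return An object of class `search_window`.
#' @export
search_window <- function(axis1, axis2 = axis1, bearing = 0,
                          min_neighbors = 3L, max_neighbors = 15L) {
  stopifnot(is.numeric(axis1), is.numeric(axis2), axis2 > 0, axis1 >= axis2)
  min_neighbors <- as.integer(min_neighbors)
  max_neighbors <- as.integer(max_neighbors)
  if (min_neighbors < 1L || max_neighbors < min_neighbors)
    stop("need 1 <= min_neighbors <= max_neighbors")
  structure(list(axis1 = as.numeric(axis1), axis2 = as.numeric(axis2),
                 bearing = as.numeric(bearing),
                 min_neighbors = min_neighbors,
                 max_neighbors = max_neighbors),
            class = "search_window")
}

#' @export
print.search_window <- function(x, ...) {
  cat(sprintf("search_window: %g x %g m ellipse, bearing %g deg, %d-%d neighbors\n",
              x$axis1, x$axis2, x$bearing, x$min_neighbors, x$max_neighbors))
  invisible(x)
}

#' Interpolator configuration
#'
#' Bundles everything one prediction needs: the method, its
#' method-specific parameter (IDW power or OK variogram model) and the
#' search window.
#'
#' @param method `"IDW"` or `"OK"`.
#' @param power IDW inverse-distance exponent (> 0); ignored for OK.
#' @param variogram a fitted [variogram_model()]; required for OK.
#' @param window a [search_window()].
#' @param clamp_to_range clamp predictions into `[0, 100]`? Kriging weights
#'   can be negative, so OK predictions may leave the data range; clamping is
#'   the only mechanism that enforces physical cover bounds.
#' @return An object of class `interp_config`.
#' @export
interp_config <- function(method = c("IDW", "OK"), power = 2,
                          variogram = NULL,
                          window = search_window(100, 100),
                          clamp_to_range = FALSE) {
  method <- match.arg(toupper(method[1L]), c("IDW", "OK"))
  stopifnot(inherits(window, "search_window"))
  if (method == "IDW") {
    stopifnot(is.numeric(power), length(power) == 1L, power > 0)
    variogram <- NULL
  } else {
    if (!inherits(variogram, "variogram_model"))
      stop("OK requires a fitted variogram_model")
    power <- NULL
  }
  structure(list(method = method, power = power, variogram = variogram,
                 window = window, clamp_to_range = isTRUE(clamp_to_range)),
            class = "interp_config")
}

#' @export
print.interp_config <- function(x, ...) {
  if (x$method == "IDW") {
    cat(sprintf("interp_config: IDW, power %g\n", x$power))
  } else {
    cat("interp_config: OK with ")
    print(x$variogram)
  }
  print(x$window)
  invisible(x)
}

# Squared elliptical "distance" of points to a location: <= 1 means inside
# the window. bearing measured clockwise from north (+y).
ellipse_metric <- function(dx, dy, window) {
  th <- window$bearing * pi / 180
  u <- dx * sin(th) + dy * cos(th)     # along major axis
  v <- dx * cos(th) - dy * sin(th)     # along minor axis
  (u / (window$axis1 / 2))^2 + (v / (window$axis2 / 2))^2
}

#' Find the neighbours of a location
#'
#' Returns the indices of the samples falling inside the search ellipse,
#' sorted by Euclidean distance (ascending) and truncated to
#' `max_neighbors`. Distance ties are broken deterministically by transect
#' id, then position index, then input order, so results are reproducible
#' across platforms.
#'
#' @param samples a `reef_samples` data frame (needs `x`, `y`; `transect_id`
#'   and `position_index` are used for tie-breaking when present).
#' @param location numeric vector `c(x, y)`.
#' @param window a [search_window()].
#' @return Integer vector of row indices (possibly empty, and shorter than
#'   `min_neighbors` — callers decide how to react), with the Euclidean
#'   distances in attribute `"distance"`.
#' @export
find_neighbors <- function(samples, location, window) {
  stopifnot(length(location) == 2L, inherits(window, "search_window"))
  dx <- samples$x - location[1L]
  dy <- samples$y - location[2L]
  inside <- which(ellipse_metric(dx, dy, window) <= 1)
  if (length(inside) == 0L)
    return(structure(integer(0), distance = numeric(0)))
  d <- sqrt(dx[inside]^2 + dy[inside]^2)
  tid <- if ("transect_id" %in% names(samples))
    xtfrm(samples$transect_id[inside]) else rep(0L, length(inside))
  pos <- if ("position_index" %in% names(samples))
    samples$position_index[inside] else rep(0L, length(inside))
  ord <- order(d, tid, pos, inside)
  keep <- ord[seq_len(min(length(ord), window$max_neighbors))]
  structure(inside[keep], distance = d[keep])
}

#' Inverse distance weighted prediction at a point
#'
#' Classical IDW: `zhat = sum(d_i^-p * z_i) / sum(d_i^-p)` over the window
#' neighbours. A neighbour closer than 1e-9 m makes the interpolator exact:
#' its value is returned unchanged.
#'
#' @param samples a `reef_samples` data frame.
#' @param location `c(x, y)`.
#' @param config an [interp_config()] with `method = "IDW"`.
#' @param taxon cover column to interpolate.
#' @return The predicted cover, or `NA` (NODATA) when fewer than
#'   `min_neighbors` samples fall in the window.
#' @export
idw_predict <- function(samples, location, config, taxon) {
  stopifnot(inherits(config, "interp_config"), config$method == "IDW")
  z <- sample_cover(samples, taxon)
  nb <- find_neighbors(samples, location, config$window)
  val <- idw_kernel(z, nb, attr(nb, "distance"), config$power)
  if (config$clamp_to_range && !is.na(val)) val <- min(max(val, 0), 100)
  val
}

idw_kernel <- function(z, nb, d, power, min_neighbors = 1L) {
  if (length(nb) < min_neighbors) return(NA_real_)
  if (d[1L] < 1e-9) return(z[nb[1L]])
  w <- d^(-power)
  sum(w * z[nb]) / sum(w)
}

#' Ordinary kriging prediction at a point
#'
#' Solves the ordinary kriging system over the window neighbours: weights
#' `lambda` satisfy `sum_j lambda_j gamma(x_i, x_j) + mu = gamma(x_i, x0)`
#' for every neighbour `i` with `sum lambda = 1`; the prediction is
#' `sum lambda_j z_j` and the kriging variance
#' `sum lambda_j gamma(x_j, x0) + mu`. A neighbour within 1e-9 m short-cuts
#' to that measured value with variance 0 (exact interpolation even under a
#' nugget). A singular system (coincident neighbours with no nugget) is
#' retried after averaging coincident points; if still singular the
#' prediction is NODATA.
#'
#' @inheritParams idw_predict
#' @param config an [interp_config()] with `method = "OK"`.
#' @return Named numeric vector `c(pred, var)`; both `NA` for NODATA.
#' @export
ok_predict <- function(samples, location, config, taxon) {
  stopifnot(inherits(config, "interp_config"), config$method == "OK")
  z <- sample_cover(samples, taxon)
  xy <- cbind(samples$x, samples$y)
  nb <- find_neighbors(samples, location, config$window)
  out <- ok_kernel(xy, z, nb, attr(nb, "distance"), config$variogram,
                   min_neighbors = config$window$min_neighbors)
  if (config$clamp_to_range && !is.na(out[1L]))
    out[1L] <- min(max(out[1L], 0), 100)
  out
}

ok_kernel <- function(xy, z, nb, d, model, min_neighbors = 1L) {
  if (length(nb) < min_neighbors) return(c(pred = NA_real_, var = NA_real_))
  if (d[1L] < 1e-9) return(c(pred = z[nb[1L]], var = 0))
  sol <- ok_solve(xy[nb, , drop = FALSE], z[nb], d, model)
  if (is.null(sol)) {
    # deduplicate coincident neighbours by averaging, then retry
    key <- paste(round(xy[nb, 1L] / 1e-9), round(xy[nb, 2L] / 1e-9))
    if (anyDuplicated(key)) {
      agg_z <- tapply(z[nb], key, mean)
      agg_i <- match(names(agg_z), key)
      sol <- ok_solve(xy[nb[agg_i], , drop = FALSE], as.numeric(agg_z),
                      d[agg_i], model)
    }
  }
  if (is.null(sol)) return(c(pred = NA_real_, var = NA_real_))
  sol
}

ok_solve <- function(pts, zv, d0, model) {
  k <- nrow(pts)
  G <- model_gamma(model, as.matrix(stats::dist(pts)))
  A <- rbind(cbind(G, 1), c(rep(1, k), 0))
  b <- c(model_gamma(model, d0), 1)
  sol <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  w <- sol[seq_len(k)]
  c(pred = sum(w * zv), var = sum(w * b[seq_len(k)]) + sol[k + 1L])
}

#' Predict cover on a grid
#'
#' Runs the configured interpolator at every cell centre of `grid`. Cells
#' whose window holds fewer than `min_neighbors` samples become NODATA; the
#' number of such cells is recorded in the raster provenance.
#'
#' @param samples a `reef_samples` data frame.
#' @param grid a [grid_spec()].
#' @param config an [interp_config()].
#' @param taxon cover column to interpolate.
#' @return A [cover_raster()]; for OK the kriging variance surface is
#'   attached as attribute `"variance"` (a matrix).
#' @export
predict_grid <- function(samples, grid, config, taxon) {
  stopifnot(inherits(grid, "grid_spec"), inherits(config, "interp_config"))
  z <- sample_cover(samples, taxon)
  xy <- cbind(samples$x, samples$y)
  ctr <- cell_centers(grid)
  n_cells <- nrow(ctr)
  vals <- numeric(n_cells)
  vars <- if (config$method == "OK") numeric(n_cells) else NULL
  win <- config$window
  tid <- if ("transect_id" %in% names(samples))
    xtfrm(samples$transect_id) else rep(0L, nrow(samples))
  pos <- if ("position_index" %in% names(samples))
    samples$position_index else rep(0L, nrow(samples))
  for (c_i in seq_len(n_cells)) {
    dx <- xy[, 1L] - ctr[c_i, 1L]
    dy <- xy[, 2L] - ctr[c_i, 2L]
    inside <- which(ellipse_metric(dx, dy, win) <= 1)
    if (length(inside) < win$min_neighbors) {
      vals[c_i] <- NA_real_
      if (!is.null(vars)) vars[c_i] <- NA_real_
      next
    }
    d <- sqrt(dx[inside]^2 + dy[inside]^2)
    ord <- order(d, tid[inside], pos[inside], inside)
    keep <- ord[seq_len(min(length(ord), win$max_neighbors))]
    nb <- inside[keep]; dk <- d[keep]
    if (config$method == "IDW") {
      vals[c_i] <- idw_kernel(z, nb, dk, config$power)
    } else {
      pv <- ok_kernel(xy, z, nb, dk, config$variogram)
      vals[c_i] <- pv[1L]
      vars[c_i] <- pv[2L]
    }
  }
  if (config$clamp_to_range) vals <- pmin(pmax(vals, 0), 100)
  # cell_centers order is row-major (columns vary fastest)
  m <- matrix(vals, nrow = grid$n_rows, ncol = grid$n_cols, byrow = TRUE)
  prov <- sprintf("%s; %d/%d cells NODATA", describe_config(config),
                  sum(is.na(vals)), n_cells)
  out <- cover_raster(grid, m, taxon = taxon, provenance = prov)
  if (!is.null(vars))
    attr(out, "variance") <- matrix(vars, nrow = grid$n_rows,
                                    ncol = grid$n_cols, byrow = TRUE)
  out
}

describe_config <- function(config) {
  if (config$method == "IDW") {
    sprintf("IDW p=%g, window %gx%g m", config$power, config$window$axis1,
            config$window$axis2)
  } else {
    v <- config$variogram
    sprintf("OK %s(%.3g,%.3g,%.3g), window %gx%g m", v$model_type, v$nugget,
            v$psill, v$range, config$window$axis1, config$window$axis2)
  }
}
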