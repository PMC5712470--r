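# Synthetic reef generator: Gaussian random fields with a prescribed
# variogram, a monotone zero-inflating transform to percent cover, transect
# sampling and point-count observation noise.

# Run expr with a fixed RNG seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic substream seed derivation; stays below 2^31 - 1.
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 100003 + k) %% 2147483647)
}

#' Simulate a zero-mean Gaussian random field on a grid
#'
#' Draws one realisation of a stationary, isotropic Gaussian field whose
#' covariance is implied by a semivariogram model, `C(h) = sill - gamma(h)`.
#' Two generation paths are available: an exact dense Cholesky factorisation
#' of the full cell-to-cell covariance (quadratic memory, used by default up
#' to 2500 cells) and circulant embedding via 2-D FFT for larger grids. The
#' circulant path is exact on its embedding torus; eigenvalues that come out
#' (slightly) negative are clamped to zero, and a warning is issued if the
#' clamped mass is non-negligible.
#'
#' @param grid a [grid_spec()].
#' @param model a [variogram_model()] (its sill sets the field variance).
#' @param seed integer seed; the same `(grid, model, seed, method)` always
#'   yields a bit-identical field.
#' @param method `"auto"` (dense when `n_cells <= dense_limit`), `"dense"`
#'   or `"circulant"`.
#' @param dense_limit cell-count threshold for the auto choice.
#' @return A `n_rows x n_cols` matrix in the internal lower-left-origin
#'   layout (`[i, j]` = grid row `i - 1`, column `j - 1`).
#' @export
simulate_gaussian_field <- function(grid, model, seed,
                                    method = c("auto", "dense", "circulant"),
                                    dense_limit = 2500) {
  stopifnot(inherits(grid, "grid_spec"), inherits(model, "variogram_model"))
  method <- match.arg(method)
  n <- grid$n_rows * grid$n_cols
  if (method == "auto") method <- if (n <= dense_limit) "dense" else "circulant"
  sill <- model$nugget + model$psill
  if (sill <= 0) return(matrix(0, grid$n_rows, grid$n_cols))
  if (method == "dense") {
    ctr <- cell_centers(grid)
    C <- model_cov(model, as.matrix(stats::dist(ctr)))
    U <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(U)) {  # tiny ridge against numerically semi-definite cases
      U <- tryCatch(chol(C + diag(1e-8 * sill, n)), error = function(e) NULL)
      if (is.null(U))
        stop(sprintf(
          "covariance matrix not positive definite for %s(%g, %g, %g) on a %d x %d grid",
          model$model_type, model$nugget, model$psill, model$range,
          grid$n_rows, grid$n_cols))
    }
    z <- with_seed(seed, stats::rnorm(n))
    vals <- as.numeric(crossprod(U, z))
    # cell_centers order is row-major (columns fastest)
    return(matrix(vals, nrow = grid$n_rows, ncol = grid$n_cols, byrow = TRUE))
  }
  # circulant embedding
  Mx <- stats::nextn(2L * grid$n_cols)
  My <- stats::nextn(2L * grid$n_rows)
  dx <- grid$cell_size * pmin(0:(Mx - 1L), Mx - (0:(Mx - 1L)))
  dy <- grid$cell_size * pmin(0:(My - 1L), My - (0:(My - 1L)))
  D <- sqrt(outer(dy^2, dx^2, "+"))
  C <- model_cov(model, D)
  lam <- Re(stats::fft(C))
  neg <- lam < 0
  if (any(neg)) {
    frac <- sum(abs(lam[neg])) / sum(abs(lam))
    if (frac > 1e-3)
      warning(sprintf(
        "circulant embedding clamped %.2f%% negative eigenvalue mass; field covariance is approximate",
        100 * frac))
    lam[neg] <- 0
  }
  eps <- with_seed(seed, matrix(complex(real = stats::rnorm(My * Mx),
                                        imaginary = stats::rnorm(My * Mx)),
                                My, Mx))
  F <- stats::fft(sqrt(lam) * eps) / sqrt(Mx * My)
  Re(F)[seq_len(grid$n_rows), seq_len(grid$n_cols), drop = FALSE]
}

#' Taxon simulation profile
#'
#' Target marginal structure for one simulated taxon: mean percent cover,
#' coefficient of variation, fraction of exact zeros, a saturation cover
#' (the highest cover the taxon sustains inside its densest patches — cover
#' plateaus there rather than spiking in single cells) and the variogram
#' controlling its spatial patch structure (on the latent standard-normal
#' scale; the sill is only used to standardise the latent field).
#'
#' @param name taxon label.
#' @param mean_cover target mean cover, percent in `[0, 100]`.
#' @param cv target coefficient of variation (sd / mean), >= 0.
#' @param zero_fraction target fraction of exact-zero cells, in `[0, 1)`.
#' @param variogram a [variogram_model()] for the latent field.
#' @param max_cover saturation cover, percent in `(0, 100]`; cells whose
#'   transformed value would exceed it are held at this plateau.
#' @return An object of class `taxon_profile`.
#' @export
taxon_profile <- function(name, mean_cover, cv, zero_fraction, variogram,
                          max_cover = 100) {
  stopifnot(is.character(name), length(name) == 1L,
            mean_cover >= 0, mean_cover <= 100, cv >= 0,
            zero_fraction >= 0, zero_fraction < 1,
            inherits(variogram, "variogram_model"),
            max_cover > 0, max_cover <= 100, mean_cover <= max_cover)
  structure(list(name = name, mean_cover = mean_cover, cv = cv,
                 zero_fraction = zero_fraction, variogram = variogram,
                 max_cover = max_cover),
            class = "taxon_profile")
}

#' @export
print.taxon_profile <- function(x, ...) {
  cat(sprintf("taxon_profile '%s': mean %g%%, CV %g, %g%% zeros, patch range %g m\n",
              x$name, x$mean_cover, x$cv, 100 * x$zero_fraction,
              x$variogram$range))
  invisible(x)
}

#' Default five-taxon reef fixture
#'
#' Simulation profiles for the five habitat-forming groups, qualitatively
#' patterned on a turbid-water Gulf-of-Mexico patch reef: abundant, smooth
#' macroalgae saturating at full cover in dense stands; moderately abundant
#' octocorals with patches up to 85%; and sparse, strongly skewed,
#' zero-inflated high-CV sponges, zoantharians and *Millepora* whose
#' densest patches plateau near 25%, 45% and 30% cover. The latent fields
#' are nugget-free — patches are smooth at the quadrat scale, and all
#' short-scale variability enters through point-count observation noise.
#' The parameters are plausible field values chosen for the simulation
#' study, not estimates of any particular reef.
#'
#' @return Named list of [taxon_profile()] objects, with the high-CV subset
#'   in attribute `"high_cv"`.
#' @export
reef_taxa <- function() {
  tx <- list(
    macroalgae = taxon_profile("macroalgae", 55, 0.45, 0,
      variogram_model("spherical", nugget = 0, psill = 1, range = 80),
      max_cover = 100),
    octocorals = taxon_profile("octocorals", 25, 0.9, 0.05,
      variogram_model("spherical", nugget = 0, psill = 1, range = 50),
      max_cover = 85),
    sponges = taxon_profile("sponges", 5, 1.6, 0.60,
      variogram_model("spherical", nugget = 0, psill = 1, range = 25),
      max_cover = 25),
    zoantharians = taxon_profile("zoantharians", 5, 2.0, 0.65,
      variogram_model("spherical", nugget = 0, psill = 1, range = 20),
      max_cover = 45),
    millepora = taxon_profile("millepora", 3, 2.2, 0.70,
      variogram_model("spherical", nugget = 0, psill = 1, range = 20),
      max_cover = 30))
  attr(tx, "high_cv") <- c("sponges", "zoantharians", "millepora")
  tx
}

# Moment-match the zero-inflated exponential transform
#   f(u) = 0                      for u <= qnorm(p0)
#        = min(M, exp(a + b u))   for u >  qnorm(p0)
# of a standard normal u so that E[f] = mean and sd/mean = cv, where M is
# the saturation cover. Returns list(a, b, q, realised_mean, realised_cv).
match_cover_moments <- function(mean_cover, cv, zero_fraction,
                                max_cover = 100, tol = 0.05) {
  q <- if (zero_fraction > 0) stats::qnorm(zero_fraction) else -Inf
  lo <- max(q, -8.5)
  u <- seq(lo, 8.5, length.out = 4000L)
  du <- u[2L] - u[1L]
  phi <- stats::dnorm(u)
  moments <- function(a, b) {
    f <- pmin(exp(a + b * u), max_cover)
    m1 <- sum(f * phi) * du
    m2 <- sum(f^2 * phi) * du
    c(m1, m2)
  }
  t1 <- mean_cover
  t2 <- mean_cover^2 * (1 + cv^2)
  b0 <- sqrt(log(1 + cv^2))
  a0 <- log(max(mean_cover, 1e-6) / (1 - zero_fraction)) - b0^2 / 2
  obj <- function(par) {
    m <- moments(par[1L], exp(par[2L]))
    log(m[1L] / t1)^2 + log(m[2L] / t2)^2
  }
  fit <- stats::optim(c(a0, log(max(b0, 1e-3))), obj,
                      control = list(maxit = 2000, reltol = 1e-12))
  a <- fit$par[1L]; b <- exp(fit$par[2L])
  m <- moments(a, b)
  r_mean <- m[1L]
  r_cv <- sqrt(max(m[2L] - m[1L]^2, 0)) / m[1L]
  if (abs(r_mean / t1 - 1) > tol || (cv > 0 && abs(r_cv / cv - 1) > tol))
    stop(sprintf(paste0(
      "unattainable cover profile: requested mean %.3g / CV %.3g / zeros %.2f ",
      "but transform realises mean %.3g / CV %.3g after clamping to [0, %g]"),
      mean_cover, cv, zero_fraction, r_mean, r_cv, max_cover))
  list(a = a, b = b, q = q, realised_mean = r_mean, realised_cv = r_cv)
}

#' Transform a Gaussian field to a percent-cover field
#'
#' Applies a monotone, zero-inflating transform to an (approximately)
#' standard Gaussian field: values below the `zero_fraction` quantile map to
#' exactly 0, and the remainder through `min(max_cover, exp(a + b u))` with
#' `(a, b)` solved numerically so that the realised mean and coefficient of
#' variation match the profile targets. The transform is non-decreasing, so
#' the spatial patch structure of the latent field is preserved, and dense
#' patches saturate at the profile's `max_cover` plateau rather than
#' spiking cell-by-cell; output always lies in `[0, 100]`.
#'
#' @param gauss_field numeric matrix, approximately N(0, 1) marginally (e.g.
#'   a [simulate_gaussian_field()] draw divided by its model sill's square
#'   root).
#' @param profile a [taxon_profile()].
#' @return Matrix of percent cover, same dimensions as `gauss_field`.
#' @export
transform_to_cover <- function(gauss_field, profile) {
  stopifnot(is.numeric(gauss_field), inherits(profile, "taxon_profile"))
  if (profile$cv == 0 && profile$zero_fraction == 0) {
    out <- gauss_field
    out[] <- profile$mean_cover
    return(out)
  }
  mm <- match_cover_moments(profile$mean_cover, profile$cv,
                            profile$zero_fraction, profile$max_cover)
  out <- pmin(exp(mm$a + mm$b * gauss_field), profile$max_cover)
  out[gauss_field <= mm$q] <- 0
  out
}

#' Photo-transect sampling design
#'
#' Parallel straight transects, sampled at regular intervals. The sampling
#' convention is half-open: the first point sits at offset 0 and the last
#' strictly before `transect_length`, so a 200 m transect sampled every 5 m
#' carries exactly 40 points. With `bearing = 0` transects run due north and
#' are offset eastward by `transect_spacing`.
#'
#' @param n_transects number of transects.
#' @param transect_length transect length, metres.
#' @param transect_spacing distance between adjacent transects, metres.
#' @param point_spacing distance between successive sampling points, metres.
#' @param origin `c(x, y)` of the first point of the first transect.
#' @param bearing transect direction, degrees clockwise from north.
#' @return An object of class `transect_design`.
#' @export
transect_design <- function(n_transects = 15, transect_length = 200,
                            transect_spacing = 200, point_spacing = 5,
                            origin = c(0, 0), bearing = 0) {
  stopifnot(n_transects >= 1, point_spacing > 0,
            transect_length >= point_spacing, transect_spacing > 0,
            length(origin) == 2L)
  structure(list(n_transects = as.integer(n_transects),
                 transect_length = transect_length,
                 transect_spacing = transect_spacing,
                 point_spacing = point_spacing,
                 origin = as.numeric(origin), bearing = as.numeric(bearing)),
            class = "transect_design")
}

#' @export
print.transect_design <- function(x, ...) {
  cat(sprintf(
    "transect_design: %d transects x %g m (spacing %g m), points every %g m (%d per transect)\n",
    x$n_transects, x$transect_length, x$transect_spacing, x$point_spacing,
    floor(x$transect_length / x$point_spacing)))
  invisible(x)
}

# Point coordinates of a design: data.frame x, y, transect_id, position_index.
design_points <- function(design) {
  np <- floor(design$transect_length / design$point_spacing)
  th <- design$bearing * pi / 180
  along <- c(sin(th), cos(th))
  across <- c(cos(th), -sin(th))
  tt <- rep(seq_len(design$n_transects) - 1L, each = np)
  kk <- rep(seq_len(np) - 1L, times = design$n_transects)
  x <- design$origin[1L] + tt * design$transect_spacing * across[1L] +
    kk * design$point_spacing * along[1L]
  y <- design$origin[2L] + tt * design$transect_spacing * across[2L] +
    kk * design$point_spacing * along[2L]
  data.frame(x = x, y = y,
             transect_id = sprintf("T%02d", tt + 1L),
             position_index = kk)
}

#' Sample one or more cover fields along photo-transects
#'
#' Reads each field at the cell containing every transect point
#' (nearest-centre rule) and assembles a `reef_samples` table. An error
#' names the first transect point that leaves the grid extent.
#'
#' @param fields a single matrix / [cover_raster()], or a named list of them
#'   (one per taxon, shared grid).
#' @param grid the [grid_spec()] the fields live on (ignored when
#'   `cover_raster`s are supplied).
#' @param design a [transect_design()].
#' @param mask optional logical vector, one entry per designed point
#'   (`TRUE` = keep); emulates field campaigns that dropped some quadrats.
#' @return A `reef_samples` data frame with columns `x`, `y`, `transect_id`,
#'   `position_index` and one cover column per taxon.
#' @export
sample_transects <- function(fields, grid = NULL, design = transect_design(),
                             mask = NULL) {
  if (inherits(fields, "cover_raster")) fields <- list(cover = fields)
  if (is.matrix(fields)) fields <- list(cover = fields)
  stopifnot(is.list(fields), length(fields) >= 1L)
  taxa <- names(fields)
  if (is.null(taxa) || any(taxa == ""))
    stop("fields must be named by taxon")
  if (is.null(grid)) {
    for (f in fields)
      if (inherits(f, "cover_raster")) { grid <- f$grid; break }
    if (is.null(grid))
      stop("grid must be supplied when fields are bare matrices")
  }
  mats <- lapply(fields, function(f)
    if (inherits(f, "cover_raster")) f$values else f)
  pts <- design_points(design)
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), length(mask) == nrow(pts))
    pts <- pts[mask, , drop = FALSE]
    # keep position_index consecutive from 0 within each transect
    pts$position_index <- stats::ave(pts$position_index, pts$transect_id,
                                     FUN = function(v) seq_along(v) - 1L)
    rownames(pts) <- NULL
  }
  idx <- cell_index(grid, pts$x, pts$y)
  for (tx in taxa) pts[[tx]] <- mats[[tx]][idx]
  as_reef_samples(pts, taxa)
}

#' Degrade cover values with point-count observation noise
#'
#' Emulates percent-cover estimation from photo-quadrats by the point-count
#' method: each true cover `z` is replaced by `100 * B / k` with
#' `B ~ Binomial(k, z / 100)`, independently per record and per taxon.
#'
#' @param samples a `reef_samples` data frame.
#' @param points_per_quadrat number of classified points per photograph
#'   (`k >= 1`); 25 by default.
#' @param seed integer seed.
#' @return The samples with every cover column resampled.
#' @export
apply_point_count_noise <- function(samples, points_per_quadrat = 25, seed) {
  stopifnot(points_per_quadrat >= 1)
  k <- as.integer(points_per_quadrat)
  taxa <- sample_taxa(samples)
  with_seed(seed, {
    for (tx in taxa) {
      z <- samples[[tx]]
      samples[[tx]] <- 100 * stats::rbinom(length(z), k, z / 100) / k
    }
  })
  samples
}

#' Thin samples to a coarser along-transect spacing
#'
#' Keeps every `factor`-th point of each transect (those with
#' `position_index` divisible by `factor`) and renumbers the survivors
#' consecutively, so that thinning by 2 twice equals thinning by 4. From a
#' 5 m base design, factors 2 and 4 emulate 10 m and 20 m sampling and
#' remove exactly 50% and 75% of the points.
#'
#' @param samples a `reef_samples` data frame with `position_index`.
#' @param factor positive integer thinning factor.
#' @return The thinned `reef_samples`.
#' @export
thin_by_spacing <- function(samples, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1L)
  if (!"position_index" %in% names(samples))
    stop("samples carry no position_index; cannot thin by spacing")
  if (factor == 1L) return(samples)
  keep <- samples$position_index %% factor == 0L
  out <- samples[keep, , drop = FALSE]
  out$position_index <- out$position_index %/% factor
  rownames(out) <- NULL
  out
}

#' Grid covering the default reef design
#'
#' A 5 m-resolution grid spanning the default 15-transect design (2900 m
#' east-west, 200 m north-south).
#'
#' @param cell_size cell size, metres.
#' @return A [grid_spec()].
#' @export
reef_grid <- function(cell_size = 5) {
  grid_spec(0, 0, n_cols = as.integer(2900 / cell_size),
            n_rows = as.integer(200 / cell_size), cell_size = cell_size)
}

#' Simulate a full synthetic reef survey
#'
#' End-to-end generator: draws one latent Gaussian field per taxon,
#' transforms each to percent cover, samples the fields along the transect
#' design and (optionally) adds point-count observation noise. Each taxon
#' and the noise stage use deterministic substreams of `seed`, so any stage
#' can be reproduced in isolation.
#'
#' @param seed integer seed.
#' @param taxa named list of [taxon_profile()]s; [reef_taxa()] by default.
#' @param grid a [grid_spec()]; [reef_grid()] by default.
#' @param design a [transect_design()]; the 15 x 200 m default.
#' @param points_per_quadrat point-count density; `NULL` or `Inf` disables
#'   observation noise.
#' @param mask optional point mask, see [sample_transects()].
#' @return A list with `samples` (a `reef_samples` data frame), `fields`
#'   (named list of [cover_raster()]s), `grid` and `design`.
#' @examples
#' reef <- simulate_reef(seed = 1, grid = grid_spec(0, 0, 60, 40, 5),
#'                       design = transect_design(n_transects = 2,
#'                                                transect_spacing = 100))
#' head(reef$samples)
#' @export
simulate_reef <- function(seed, taxa = reef_taxa(), grid = reef_grid(),
                          design = transect_design(),
                          points_per_quadrat = 25, mask = NULL) {
  stopifnot(is.list(taxa), length(taxa) >= 1L)
  fields <- list()
  for (k in seq_along(taxa)) {
    pr <- taxa[[k]]
    sill <- pr$variogram$nugget + pr$variogram$psill
    g <- simulate_gaussian_field(grid, pr$variogram, sub_seed(seed, k))
    cov_field <- transform_to_cover(g / sqrt(sill), pr)
    fields[[pr$name]] <- cover_raster(grid, cov_field, taxon = pr$name,
                                      provenance = sprintf("simulated, seed %d",
                                                           sub_seed(seed, k)))
  }
  samples <- sample_transects(fields, grid = grid, design = design,
                              mask = mask)
  if (!is.null(points_per_quadrat) && is.finite(points_per_quadrat))
    samples <- apply_point_count_noise(samples, points_per_quadrat,
                                       seed = sub_seed(seed, 999L))
  list(samples = samples, fields = fields, grid = grid, design = design)
}
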