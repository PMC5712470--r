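# Leave-one-out cross-validation, accuracy metrics, per-method model
# selection and the multi-distance method comparison.

#' Mean absolute error of prediction pairs
#'
#' `ME = mean(|predicted - measured|)` — the mean of the absolute errors,
#' in percent-cover units.
#'
#' @param pairs a data frame or two-column matrix with measured values in
#'   the first column and predicted in the second.
#' @return A single non-negative number.
#' @export
mean_error <- function(pairs) {
  p <- as_pairs(pairs)
  if (nrow(p) == 0L) stop("no prediction pairs")
  mean(abs(p[, 2L] - p[, 1L]))
}

#' Squared correlation of predicted against measured values
#'
#' The squared Pearson correlation, identical to the coefficient of
#' determination of the simple regression of either variable on the other.
#' Undefined (returns `NA`) with fewer than 3 pairs or when either side has
#' zero variance.
#'
#' @inheritParams mean_error
#' @return `r2` in `[0, 1]`, or `NA` when undefined.
#' @export
r_squared <- function(pairs) {
  p <- as_pairs(pairs)
  if (nrow(p) < 3L) return(NA_real_)
  if (stats::var(p[, 1L]) == 0 || stats::var(p[, 2L]) == 0) return(NA_real_)
  stats::cor(p[, 1L], p[, 2L])^2
}

as_pairs <- function(pairs) {
  if (is.data.frame(pairs)) pairs <- as.matrix(pairs[, 1:2, drop = FALSE])
  stopifnot(is.matrix(pairs), ncol(pairs) >= 2L)
  pairs <- pairs[, 1:2, drop = FALSE]
  pairs[stats::complete.cases(pairs), , drop = FALSE]
}

#' Quartile / outlier summary of a vector
#'
#' Quartiles by linear interpolation between order statistics (the default
#' box-plot convention) and Tukey outliers beyond `1.5 * IQR` fences.
#'
#' @param values numeric vector (at least one finite value).
#' @return A list with `q1`, `median`, `q3`, `iqr`, `lower_fence`,
#'   `upper_fence` and the `outliers` values.
#' @export
distribution_summary <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("no finite values to summarise")
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3L] - q[1L]
  lo <- q[1L] - 1.5 * iqr
  hi <- q[3L] + 1.5 * iqr
  list(q1 = q[1L], median = q[2L], q3 = q[3L], iqr = iqr,
       lower_fence = lo, upper_fence = hi,
       outliers = values[values < lo | values > hi])
}

#' Leave-one-out cross-validation of an interpolator
#'
#' Removes each sample in turn, predicts at its location from the remaining
#' points under `config`, and pairs prediction with measurement. Locations
#' whose window retains fewer than `min_neighbors` other samples get no
#' prediction; they are excluded from the metrics and counted in
#' `n_nodata`. The procedure is fully deterministic.
#'
#' @param samples a `reef_samples` data frame.
#' @param taxon cover column to validate.
#' @param config an [interp_config()].
#' @return A `cv_report`: list with `taxon`, `method`, `config`, `pairs`
#'   (data frame `measured`, `predicted`), `ME`, `r2` (`NA` when
#'   undefined), `n`, `n_nodata` and quartile `summary` of both series.
#' @export
loo_crossval <- function(samples, taxon, config) {
  stopifnot(inherits(config, "interp_config"))
  z <- sample_cover(samples, taxon)
  n <- length(z)
  win <- config$window
  if (n < win$min_neighbors + 1L)
    stop("need at least min_neighbors + 1 samples for leave-one-out")
  x <- samples$x; y <- samples$y
  DX <- outer(x, x, "-")   # DX[i, j] = x_j - x_i as seen from location i
  DY <- outer(y, y, "-")
  DX <- -DX; DY <- -DY
  D <- sqrt(DX^2 + DY^2)
  E <- ellipse_metric(DX, DY, win)
  G <- if (config$method == "OK") model_gamma(config$variogram, D) else NULL
  tid <- if ("transect_id" %in% names(samples)) xtfrm(samples$transect_id)
         else rep(0L, n)
  pos <- if ("position_index" %in% names(samples)) samples$position_index
         else rep(0L, n)
  xy <- cbind(x, y)
  pred <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    cand <- which(E[i, ] <= 1)
    cand <- cand[cand != i]
    if (length(cand) < win$min_neighbors) next
    d <- D[i, cand]
    ord <- order(d, tid[cand], pos[cand], cand)
    keep <- ord[seq_len(min(length(ord), win$max_neighbors))]
    nb <- cand[keep]; dk <- d[keep]
    if (config$method == "IDW") {
      pred[i] <- idw_kernel(z, nb, dk, config$power)
    } else {
      k <- length(nb)
      if (dk[1L] < 1e-9) { pred[i] <- z[nb[1L]]; next }
      A <- rbind(cbind(G[nb, nb, drop = FALSE], 1), c(rep(1, k), 0))
      b <- c(G[nb, i], 1)
      sol <- tryCatch(solve(A, b), error = function(e) NULL)
      pred[i] <- if (is.null(sol))
        ok_kernel(xy, z, nb, dk, config$variogram)[1L]
      else sum(sol[seq_len(k)] * z[nb])
    }
  }
  if (config$clamp_to_range) pred <- pmin(pmax(pred, 0), 100)
  ok <- !is.na(pred)
  pairs <- data.frame(measured = z[ok], predicted = pred[ok])
  new_cv_report(taxon, config, pairs, n = n, n_nodata = sum(!ok))
}

new_cv_report <- function(taxon, config, pairs, n, n_nodata) {
  has_pairs <- nrow(pairs) > 0L
  structure(list(
    taxon = taxon, method = config$method, config = config, pairs = pairs,
    ME = if (has_pairs) mean_error(pairs) else NA_real_,
    r2 = if (has_pairs) r_squared(pairs) else NA_real_,
    n = n, n_nodata = n_nodata,
    summary = if (has_pairs)
      list(measured = distribution_summary(pairs$measured),
           predicted = distribution_summary(pairs$predicted))
    else NULL), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report [%s, %s]: %d/%d predicted (%d NODATA)\n",
              x$taxon, describe_config(x$config), nrow(x$pairs), x$n,
              x$n_nodata))
  cat(sprintf("  ME = %.4g, r2 = %s\n", x$ME,
              if (is.na(x$r2)) "undefined" else sprintf("%.4g", x$r2)))
  invisible(x)
}

#' Select the best interpolator configuration by cross-validation
#'
#' Runs [loo_crossval()] for every candidate and returns the configuration
#' minimising ME; ties are broken by higher r-squared, then by candidate
#' order. IDW candidates are powers; OK candidates are variogram model
#' families (fitted here to the samples' empirical variogram) or
#' pre-fitted [variogram_model()] objects.
#'
#' @param samples a `reef_samples` data frame.
#' @param taxon cover column.
#' @param method `"IDW"` or `"OK"`.
#' @param candidates numeric powers (IDW; default 1, 2, 3) or for OK a
#'   character vector of model families (default spherical, exponential) or
#'   a list of `variogram_model`s.
#' @param window shared [search_window()].
#' @param lag_width,max_lag variography controls for OK family fitting; the
#'   defaults take the sampling spacing and 100 m.
#' @param clamp_to_range passed to [interp_config()].
#' @return A list with the winning `config`, its cv `report` and the
#'   per-candidate score `table`.
#' @export
select_best_config <- function(samples, taxon, method = c("IDW", "OK"),
                               candidates = NULL,
                               window = search_window(100, 100),
                               lag_width = NULL, max_lag = 100,
                               clamp_to_range = FALSE) {
  method <- match.arg(toupper(method[1L]), c("IDW", "OK"))
  if (is.null(candidates))
    candidates <- if (method == "IDW") c(1, 2, 3)
                  else c("spherical", "exponential")
  configs <- list(); labels <- character()
  if (method == "IDW") {
    for (p in candidates) {
      configs[[length(configs) + 1L]] <-
        interp_config("IDW", power = p, window = window,
                      clamp_to_range = clamp_to_range)
      labels <- c(labels, sprintf("p=%g", p))
    }
  } else {
    if (is.character(candidates)) {
      emp <- empirical_variogram(samples, taxon, lag_width = lag_width,
                                 max_lag = max_lag)
      candidates <- lapply(candidates, function(ct) fit_variogram(emp, ct))
    }
    if (inherits(candidates, "variogram_model")) candidates <- list(candidates)
    for (vm in candidates) {
      configs[[length(configs) + 1L]] <-
        interp_config("OK", variogram = vm, window = window,
                      clamp_to_range = clamp_to_range)
      labels <- c(labels, vm$model_type)
    }
  }
  stopifnot(length(configs) >= 1L)
  reports <- lapply(configs, function(cfg) loo_crossval(samples, taxon, cfg))
  me <- vapply(reports, function(r) if (is.na(r$ME)) Inf else r$ME, numeric(1))
  r2 <- vapply(reports, function(r) if (is.na(r$r2)) -Inf else r$r2, numeric(1))
  ord <- order(me, -r2, seq_along(configs))
  best <- ord[1L]
  tab <- data.frame(candidate = labels, ME = me, r2 = r2,
                    n_pairs = vapply(reports, function(r) nrow(r$pairs),
                                     integer(1)),
                    n_nodata = vapply(reports, function(r) r$n_nodata,
                                      integer(1)))
  tab$r2[!is.finite(tab$r2)] <- NA_real_
  tab$ME[!is.finite(tab$ME)] <- NA_real_
  list(config = configs[[best]], report = reports[[best]],
       candidate = labels[best], table = tab)
}

#' Compare IDW and OK across taxa and sampling distances
#'
#' The full comparison protocol: for every taxon and every thinning factor,
#' select the best IDW power and the best OK variogram family by
#' leave-one-out cross-validation (one shared search window for both
#' methods), and tabulate the winning configuration's accuracy. From a 5 m
#' base design, thinning factors 1, 2 and 4 correspond to 5, 10 and 20 m
#' sampling distances.
#'
#' @param samples base-spacing `reef_samples`.
#' @param taxa cover columns to compare (default: all).
#' @param thinning_factors integer factors (default `c(1, 2, 4)`).
#' @param idw_powers candidate IDW powers.
#' @param ok_models candidate OK variogram families.
#' @param window shared [search_window()].
#' @param max_lag variography max lag, metres.
#' @return A long-format data frame with one row per taxon x factor x
#'   method: `taxon`, `factor`, `spacing_factor` label, `method`,
#'   `candidate`, `ME`, `r2`, `n_pairs`, `n_nodata`, `max_measured`,
#'   `max_predicted`, and quartiles of both series (`meas_q1`...,
#'   `pred_q3`). Attribute `"candidates"` holds the per-candidate score
#'   tables.
#' @export
compare_methods <- function(samples, taxa = NULL,
                            thinning_factors = c(1, 2, 4),
                            idw_powers = c(1, 2, 3),
                            ok_models = c("spherical", "exponential"),
                            window = search_window(100, 100),
                            max_lag = 100) {
  if (is.null(taxa)) taxa <- sample_taxa(samples)
  rows <- list(); cand_tabs <- list()
  for (f in thinning_factors) {
    thinned <- thin_by_spacing(samples, f)
    for (tx in taxa) {
      for (method in c("IDW", "OK")) {
        candidates <- if (method == "IDW") idw_powers else ok_models
        sel <- tryCatch(
          select_best_config(thinned, tx, method, candidates,
                             window = window, max_lag = max_lag),
          error = function(e) NULL)
        key <- sprintf("%s|f%d|%s", tx, f, method)
        if (is.null(sel)) {
          rows[[key]] <- data.frame(
            taxon = tx, factor = f, method = method,
            candidate = NA_character_, ME = NA_real_, r2 = NA_real_,
            n_pairs = 0L, n_nodata = NA_integer_,
            max_measured = NA_real_, max_predicted = NA_real_,
            meas_q1 = NA_real_, meas_median = NA_real_, meas_q3 = NA_real_,
            pred_q1 = NA_real_, pred_median = NA_real_, pred_q3 = NA_real_)
          next
        }
        rep <- sel$report
        sm <- rep$summary
        rows[[key]] <- data.frame(
          taxon = tx, factor = f, method = method, candidate = sel$candidate,
          ME = rep$ME, r2 = rep$r2, n_pairs = nrow(rep$pairs),
          n_nodata = rep$n_nodata,
          max_measured = max(rep$pairs$measured),
          max_predicted = max(rep$pairs$predicted),
          meas_q1 = sm$measured$q1, meas_median = sm$measured$median,
          meas_q3 = sm$measured$q3,
          pred_q1 = sm$predicted$q1, pred_median = sm$predicted$median,
          pred_q3 = sm$predicted$q3)
        cand_tabs[[key]] <- sel$table
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "candidates") <- cand_tabs
  out
}

#' Replicate the method comparison over simulated reefs
#'
#' Monte-Carlo driver: simulates one synthetic reef per seed with
#' [simulate_reef()] and runs [compare_methods()] on each, stacking the
#' results with a `seed` column. This is the experiment behind the
#' accuracy-versus-sampling-distance and IDW-versus-OK summaries.
#'
#' @param seeds integer vector of simulation seeds.
#' @param taxa,grid,design,points_per_quadrat passed to [simulate_reef()].
#' @param ... passed to [compare_methods()].
#' @return A long data frame: `seed` plus the [compare_methods()] columns.
#' @export
replicate_comparison <- function(seeds, taxa = reef_taxa(),
                                 grid = reef_grid(),
                                 design = transect_design(),
                                 points_per_quadrat = 25, ...) {
  out <- lapply(seeds, function(s) {
    reef <- simulate_reef(s, taxa = taxa, grid = grid, design = design,
                          points_per_quadrat = points_per_quadrat)
    cmp <- compare_methods(reef$samples, ...)
    cbind(seed = s, as.data.frame(cmp))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
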