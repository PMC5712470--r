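# Independent brute-force oracles and tiny fixture builders. These never
# call the package's own computational path for the quantity they check.

# All-pairs Matheron estimator by direct double loop. Bins are centred on
# multiples of lag_width; sub-half-lag pairs join the first bin.
oracle_matheron <- function(x, y, z, lag_width, max_lag) {
  n_bins <- ceiling(max_lag / lag_width)
  ssq <- numeric(n_bins); cnt <- integer(n_bins)
  n <- length(z)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
      if (d > 0 && d < (n_bins + 0.5) * lag_width) {
        k <- max(1, floor(d / lag_width + 0.5))
        ssq[k] <- ssq[k] + (z[i] - z[j])^2
        cnt[k] <- cnt[k] + 1L
      }
    }
  }
  list(gamma = ifelse(cnt > 0, ssq / (2 * cnt), NA_real_), n_pairs = cnt)
}

# Semivariogram closed forms, written independently of model_gamma().
oracle_gamma <- function(type, c0, c1, a, h) {
  g <- vapply(h, function(hh) {
    if (hh == 0) return(0)
    s <- switch(type,
      nugget = 1,
      spherical = if (hh >= a) 1 else 1.5 * (hh / a) - 0.5 * (hh / a)^3,
      exponential = 1 - exp(-3 * hh / a),
      gaussian = 1 - exp(-3 * hh^2 / a^2))
    c0 + c1 * s
  }, numeric(1))
  g
}

# Dense global ordinary kriging over ALL points: one (n+1) x (n+1) solve.
oracle_global_ok <- function(x, y, z, type, c0, c1, a, x0, y0) {
  n <- length(z)
  D <- as.matrix(dist(cbind(x, y)))
  G <- matrix(oracle_gamma(type, c0, c1, a, as.numeric(D)), n, n)
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  d0 <- sqrt((x - x0)^2 + (y - y0)^2)
  b <- c(oracle_gamma(type, c0, c1, a, d0), 1)
  sol <- solve(A, b)
  w <- sol[seq_len(n)]
  list(pred = sum(w * z), var = sum(w * b[seq_len(n)]) + sol[n + 1],
       weights = w, mu = sol[n + 1])
}

# Direct IDW weighted mean over an explicit neighbour set.
oracle_idw <- function(z, d, p) {
  w <- d^(-p)
  sum(w * z) / sum(w)
}

# Small irregular 2-D point set with a smooth-ish surface plus noise.
toy_samples <- function(n = 20, seed = 11, taxon = "cover") {
  set.seed(seed)
  x <- runif(n, 0, 100); y <- runif(n, 0, 100)
  z <- pmin(pmax(30 + 20 * sin(x / 25) + 15 * cos(y / 30) +
                 rnorm(n, 0, 3), 0), 100)
  df <- data.frame(x = x, y = y,
                   transect_id = "T01", position_index = seq_len(n) - 1L)
  df[[taxon]] <- z
  structure(df, class = c("reef_samples", "data.frame"), taxa = taxon)
}

# A small simulated reef (fast): 4 transects, 40 points each.
small_reef <- function(seed = 5, taxa = reef_taxa()[c("macroalgae", "sponges")],
                       noise = 25) {
  simulate_reef(seed, taxa = taxa,
                grid = grid_spec(0, 0, 80, 40, 5),
                design = transect_design(n_transects = 4,
                                         transect_spacing = 100),
                points_per_quadrat = noise)
}

# Full circular window that always contains every sample of the sets above.
full_window <- function(min_neighbors = 1, max_neighbors = 10000)
  search_window(1e6, 1e6, min_neighbors = min_neighbors,
                max_neighbors = max_neighbors)
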