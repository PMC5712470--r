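# Synthetic-data module: Gaussian fields, cover transform, transect
# sampling, observation noise, thinning.

test_that("pure-nugget fields are spatially unstructured white noise", {
  g <- grid_spec(0, 0, 100, 100, 5)
  f <- simulate_gaussian_field(g, variogram_model("nugget", nugget = 1,
                                                  psill = 0, range = 1),
                               seed = 3)
  expect_equal(dim(f), c(100, 100))
  # lag-1 correlation along both axes is negligible at 1e4 cells
  rho_x <- cor(as.numeric(f[, -1]), as.numeric(f[, -100]))
  rho_y <- cor(as.numeric(f[-1, ]), as.numeric(f[-100, ]))
  expect_lt(abs(rho_x), 0.05)
  expect_lt(abs(rho_y), 0.05)
})

test_that("simulated field variance matches the model sill", {
  g <- grid_spec(0, 0, 100, 100, 5)
  m <- variogram_model("spherical", nugget = 0, psill = 1, range = 50)
  v <- vapply(1:20, function(s)
    var(as.numeric(simulate_gaussian_field(g, m, seed = s))), numeric(1))
  expect_lt(abs(mean(v) - 1), 0.15)
})

test_that("field generation is deterministic and the paths agree on moments", {
  g <- grid_spec(0, 0, 40, 25, 5)
  m <- variogram_model("exponential", nugget = 0.2, psill = 0.8, range = 40)
  expect_identical(simulate_gaussian_field(g, m, seed = 7),
                   simulate_gaussian_field(g, m, seed = 7))
  expect_false(identical(simulate_gaussian_field(g, m, seed = 7),
                         simulate_gaussian_field(g, m, seed = 8)))
  # dense and circulant are different algorithms but share the target
  # covariance; compare variances across seeds
  vd <- mean(vapply(1:10, function(s)
    var(as.numeric(simulate_gaussian_field(g, m, s, method = "dense"))),
    numeric(1)))
  vc <- mean(vapply(1:10, function(s)
    var(as.numeric(simulate_gaussian_field(g, m, s, method = "circulant"))),
    numeric(1)))
  expect_lt(abs(vd - 1), 0.2)
  expect_lt(abs(vc - 1), 0.2)
})

test_that("empirical variogram of simulated fields tracks the generating model", {
  m <- variogram_model("spherical", nugget = 0, psill = 1, range = 50)
  g <- grid_spec(0, 0, 60, 60, 5)
  gam_half <- numeric(0); gam_full <- numeric(0)
  for (s in 1:20) {
    f <- simulate_gaussian_field(g, m, seed = s)
    set.seed(s)
    idx <- sample(3600, 450)
    ctr <- cell_centers(g)
    df <- data.frame(x = ctr[idx, 1], y = ctr[idx, 2],
                     z = as.numeric(t(f))[idx])
    smp <- structure(df, class = c("reef_samples", "data.frame"), taxa = "z")
    emp <- empirical_variogram(smp, "z", lag_width = 5, max_lag = 60)
    gam_half <- c(gam_half, emp$gamma[emp$lag == 25])
    gam_full <- c(gam_full, emp$gamma[emp$lag == 50])
  }
  expect_lt(abs(mean(gam_half) / model_gamma(m, 25) - 1), 0.2)
  expect_lt(abs(mean(gam_full) / model_gamma(m, 50) - 1), 0.2)
})

test_that("cover transform hits its target moments and stays in range", {
  prof_const <- taxon_profile("c", 40, 0, 0,
                              variogram_model("spherical", 0, 1, 10))
  f <- matrix(rnorm(100), 10, 10)
  expect_true(all(transform_to_cover(f, prof_const) == 40))

  prof <- taxon_profile("s", 7, 2.0, 0.6,
                        variogram_model("spherical", 0, 1, 25))
  g <- grid_spec(0, 0, 60, 60, 5)
  means <- numeric(0); zf <- numeric(0)
  for (s in 1:20) {
    gf <- simulate_gaussian_field(g, prof$variogram, seed = 100 + s)
    cf <- transform_to_cover(gf, prof)
    expect_gte(min(cf), 0)
    expect_lte(max(cf), 100)
    means <- c(means, mean(cf)); zf <- c(zf, mean(cf == 0))
  }
  expect_lt(abs(mean(means) / 7 - 1), 0.2)
  expect_gte(mean(zf), 0.5)
  # monotone on the non-zero part
  u <- seq(-3, 3, length.out = 200)
  cv <- transform_to_cover(matrix(u, 1), prof)
  nz <- cv > 0
  expect_true(all(diff(cv[nz]) >= 0))
})

test_that("unattainable cover profiles are rejected with realised moments", {
  bad <- taxon_profile("b", 20, 3.5, 0.2,
                       variogram_model("spherical", 0, 1, 10), max_cover = 30)
  expect_error(transform_to_cover(matrix(rnorm(9), 3), bad), "unattainable")
})

test_that("transect sampling follows the half-open design convention", {
  g <- reef_grid()
  f <- matrix(42, g$n_rows, g$n_cols)
  s <- sample_transects(list(cover = f), g, transect_design())
  expect_equal(nrow(s), 15 * 40)
  expect_true(all(s$cover == 42))
  expect_equal(sort(unique(s$position_index)), 0:39)
  expect_equal(length(unique(s$transect_id)), 15)

  one <- sample_transects(list(cover = f), g,
                          transect_design(n_transects = 1,
                                          transect_length = 5,
                                          point_spacing = 5))
  expect_equal(nrow(one), 1)

  # non-constant field: values come from the containing cell
  f2 <- matrix(seq_len(g$n_rows * g$n_cols), g$n_rows, g$n_cols)
  s2 <- sample_transects(list(v = f2), g,
                         transect_design(n_transects = 2))
  expect_equal(s2$v[1], f2[1, 1])          # point (0, 0) -> cell (1, 1)
  expect_equal(s2$v[2], f2[2, 1])          # point (0, 5) -> cell (2, 1)

  expect_error(
    sample_transects(list(cover = f), g,
                     transect_design(n_transects = 20)),
    "outside the grid")
})

test_that("a point mask drops quadrats and renumbers positions", {
  g <- reef_grid()
  f <- matrix(1, g$n_rows, g$n_cols)
  mask <- rep(TRUE, 600); mask[c(3, 41, 42)] <- FALSE
  s <- sample_transects(list(cover = f), g, transect_design(), mask = mask)
  expect_equal(nrow(s), 597)
  t1 <- s$position_index[s$transect_id == "T01"]
  expect_equal(t1, 0:38)   # still consecutive from 0
})

test_that("point-count noise has binomial structure and limits", {
  df <- data.frame(x = seq_len(1e4), y = 0, transect_id = "T01",
                   position_index = seq_len(1e4) - 1L,
                   a = rep(c(0, 100, 50), length.out = 1e4))
  s <- structure(df, class = c("reef_samples", "data.frame"), taxa = "a")
  out <- apply_point_count_noise(s, 25, seed = 9)
  expect_true(all(out$a[s$a == 0] == 0))
  expect_true(all(out$a[s$a == 100] == 100))
  mid <- out$a[s$a == 50]
  expect_true(all(mid %in% seq(0, 100, by = 4)))
  expect_lt(abs(mean(mid) - 50), 1)
  # large point count recovers the truth
  fine <- apply_point_count_noise(s, 1e4, seed = 9)
  expect_lt(sd(fine$a[s$a == 50]), 1)
  # determinism
  expect_identical(apply_point_count_noise(s, 25, seed = 4),
                   apply_point_count_noise(s, 25, seed = 4))
})

test_that("thinning removes the right fractions and composes", {
  g <- reef_grid()
  f <- matrix(1, g$n_rows, g$n_cols)
  s <- sample_transects(list(cover = f), g, transect_design())
  t2 <- thin_by_spacing(s, 2)
  t4 <- thin_by_spacing(s, 4)
  expect_equal(nrow(t2), 300)       # 50% removed
  expect_equal(nrow(t4), 150)       # 75% removed
  expect_identical(thin_by_spacing(s, 1), s)
  expect_equal(thin_by_spacing(t2, 2), t4)
  expect_error(thin_by_spacing(data.frame(x = 1, y = 1, a = 1), 2),
               "position_index")
})

test_that("simulate_reef is a pure function of its seed", {
  r1 <- small_reef(seed = 31)
  r2 <- small_reef(seed = 31)
  r3 <- small_reef(seed = 32)
  expect_identical(r1$samples, r2$samples)
  expect_identical(r1$fields$sponges$values, r2$fields$sponges$values)
  expect_false(identical(r1$samples, r3$samples))
  for (tx in sample_taxa(r1$samples)) {
    expect_gte(min(r1$samples[[tx]]), 0)
    expect_lte(max(r1$samples[[tx]]), 100)
  }
})
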