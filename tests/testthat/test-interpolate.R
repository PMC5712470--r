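# Interpolators: neighbourhood search, IDW, ordinary kriging, grid
# prediction, and their exactness/convexity/equivalence properties.

test_that("circular windows reduce to Euclidean distance membership", {
  s <- toy_samples(30, seed = 2)
  win <- search_window(40, 40, min_neighbors = 1, max_neighbors = 100)
  loc <- c(50, 50)
  nb <- find_neighbors(s, loc, win)
  d_all <- sqrt((s$x - 50)^2 + (s$y - 50)^2)
  expect_setequal(nb, which(d_all <= 20))
  expect_equal(attr(nb, "distance"), sort(d_all[d_all <= 20]))
})

test_that("neighbour lists are distance-ordered and truncated", {
  s <- structure(data.frame(x = seq(0, 90, 10), y = 0, transect_id = "T01",
                            position_index = 0:9, z = 1:10),
                 class = c("reef_samples", "data.frame"), taxa = "z")
  win <- search_window(70, 70, min_neighbors = 1, max_neighbors = 4)
  nb <- find_neighbors(s, c(0, 0), win)
  expect_equal(as.integer(nb), 1:4)   # the 4 nearest, ascending distance
  nb0 <- find_neighbors(s, c(20, 0), search_window(200, 200,
                                                   max_neighbors = 100))
  expect_equal(as.integer(nb0)[1], 3L)
  expect_equal(attr(nb0, "distance")[1], 0)
})

test_that("elliptical membership honours axis lengths and rotation", {
  s <- structure(data.frame(x = c(30, 0), y = c(0, 30), z = c(1, 2)),
                 class = c("reef_samples", "data.frame"), taxa = "z")
  # major axis north (bearing 0): only the point 30 m north is inside
  win <- search_window(80, 20, bearing = 0, min_neighbors = 1)
  expect_equal(as.integer(find_neighbors(s, c(0, 0), win)), 2L)
  # rotate the major axis east: now only the eastern point is inside
  win90 <- search_window(80, 20, bearing = 90, min_neighbors = 1)
  expect_equal(as.integer(find_neighbors(s, c(0, 0), win90)), 1L)
})

test_that("IDW matches hand weights and is exact and convex", {
  s <- structure(data.frame(x = c(0, 10, 0), y = c(0, 0, 10),
                            z = c(10, 20, 30)),
                 class = c("reef_samples", "data.frame"), taxa = "z")
  cfg <- interp_config("IDW", power = 2, window = full_window())
  # weights at (2, 0) are proportional to (1/4, 1/64, 1/104)
  w <- c(1 / 4, 1 / 64, 1 / 104)
  expect_equal(idw_predict(s, c(2, 0), cfg, "z"),
               sum(w * c(10, 20, 30)) / sum(w))
  # symmetry: two equidistant values average for any power
  s2 <- structure(data.frame(x = c(-5, 5), y = 0, z = c(0, 10)),
                  class = c("reef_samples", "data.frame"), taxa = "z")
  for (p in c(1, 2, 3, 7))
    expect_equal(idw_predict(s2, c(0, 0),
                             interp_config("IDW", power = p,
                                           window = full_window()), "z"), 5)
  # exactness at a sample location
  expect_equal(idw_predict(s, c(10, 0), cfg, "z"), 20)
  # convexity: prediction within neighbour range
  s3 <- toy_samples(25, seed = 4)
  cfg3 <- interp_config("IDW", power = 2,
                        window = search_window(60, 60, min_neighbors = 1))
  for (loc in list(c(20, 20), c(50, 80), c(70, 30))) {
    nb <- find_neighbors(s3, loc, cfg3$window)
    pred <- idw_predict(s3, loc, cfg3, "cover")
    expect_gte(pred, min(s3$cover[nb]))
    expect_lte(pred, max(s3$cover[nb]))
  }
})

test_that("IDW approaches nearest-neighbour prediction at high power", {
  s <- toy_samples(25, seed = 6)
  win <- search_window(80, 80, min_neighbors = 1)
  loc <- c(33, 57)
  nb <- find_neighbors(s, loc, win)
  pred <- idw_predict(s, loc, interp_config("IDW", power = 64, window = win),
                      "cover")
  expect_equal(pred, s$cover[nb[1]], tolerance = 1e-6)
})

test_that("ordinary kriging solves the dual of the dense oracle", {
  s <- structure(data.frame(x = c(0, 40, 10), y = c(0, 0, 30),
                            z = c(12, 30, 24)),
                 class = c("reef_samples", "data.frame"), taxa = "z")
  vm <- variogram_model("spherical", nugget = 0, psill = 1, range = 50)
  cfg <- interp_config("OK", variogram = vm, window = full_window())
  loc <- c(15, 10)
  got <- ok_predict(s, loc, cfg, "z")
  orc <- oracle_global_ok(s$x, s$y, s$z, "spherical", 0, 1, 50,
                          loc[1], loc[2])
  expect_equal(unname(got["pred"]), orc$pred, tolerance = 1e-6)
  expect_equal(unname(got["var"]), orc$var, tolerance = 1e-6)
  expect_equal(sum(orc$weights), 1, tolerance = 1e-8)
})

test_that("pure-nugget kriging is the neighbour mean", {
  s <- toy_samples(12, seed = 9)
  vm <- variogram_model("nugget", nugget = 2, psill = 0, range = 1)
  cfg <- interp_config("OK", variogram = vm, window = full_window())
  got <- ok_predict(s, c(48, 52), cfg, "cover")
  expect_equal(unname(got["pred"]), mean(s$cover), tolerance = 1e-8)
})

test_that("kriging is exact at data points and shift-equivariant", {
  s <- toy_samples(15, seed = 12)
  vm <- variogram_model("exponential", nugget = 0.5, psill = 2, range = 40)
  cfg <- interp_config("OK", variogram = vm, window = full_window())
  got <- ok_predict(s, c(s$x[4], s$y[4]), cfg, "cover")
  expect_equal(unname(got["pred"]), s$cover[4])
  expect_equal(unname(got["var"]), 0)
  # adding a constant to all data shifts the prediction by that constant
  # (equivalent to the weights summing to one)
  s2 <- s; s2$cover <- s$cover + 17
  loc <- c(41, 33)
  expect_equal(unname(ok_predict(s2, loc, cfg, "cover")["pred"]),
               unname(ok_predict(s, loc, cfg, "cover")["pred"]) + 17,
               tolerance = 1e-8)
})

test_that("both interpolators are invariant under rigid motions", {
  s <- toy_samples(18, seed = 14)
  win <- search_window(90, 90, min_neighbors = 1)
  vm <- variogram_model("spherical", nugget = 0.3, psill = 1.5, range = 45)
  loc <- c(55, 45)
  base_idw <- idw_predict(s, loc, interp_config("IDW", 2, window = win),
                          "cover")
  base_ok <- ok_predict(s, loc, interp_config("OK", variogram = vm,
                                              window = win), "cover")
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  for (shift in list(c(100, -40), c(-3, 8))) {
    xy <- t(R %*% rbind(s$x, s$y)) + rep(shift, each = nrow(s))
    s2 <- s; s2$x <- xy[, 1]; s2$y <- xy[, 2]
    loc2 <- as.numeric(R %*% loc + shift)
    expect_equal(idw_predict(s2, loc2, interp_config("IDW", 2, window = win),
                             "cover"), base_idw, tolerance = 1e-9)
    got <- ok_predict(s2, loc2, interp_config("OK", variogram = vm,
                                              window = win), "cover")
    expect_equal(unname(got["pred"]), unname(base_ok["pred"]),
                 tolerance = 1e-8)
  }
})

test_that("windowed grid kriging equals the dense global oracle when the window covers all", {
  s <- toy_samples(30, seed = 17)
  vm <- variogram_model("spherical", nugget = 0.2, psill = 1.3, range = 60)
  g <- grid_spec(0, 0, 6, 5, 20)
  cfg <- interp_config("OK", variogram = vm, window = full_window())
  r <- predict_grid(s, g, cfg, "cover")
  ctr <- cell_centers(g)
  for (i in seq_len(nrow(ctr))) {
    orc <- oracle_global_ok(s$x, s$y, s$cover, "spherical", 0.2, 1.3, 60,
                            ctr[i, 1], ctr[i, 2])
    row <- (i - 1) %/% g$n_cols + 1; col <- (i - 1) %% g$n_cols + 1
    expect_equal(r$values[row, col], orc$pred, tolerance = 1e-6)
  }
})

test_that("grid prediction honours NODATA, clamping and constant fields", {
  s <- structure(data.frame(x = c(10, 20, 30), y = 15, transect_id = "T01",
                            position_index = 0:2, z = c(50, 50, 50)),
                 class = c("reef_samples", "data.frame"), taxa = "z")
  g <- grid_spec(0, 0, 20, 4, 10)
  win <- search_window(60, 60, min_neighbors = 2)
  rI <- predict_grid(s, g, interp_config("IDW", 2, window = win), "z")
  vm <- variogram_model("spherical", 0.1, 1, 30)
  rO <- predict_grid(s, g, interp_config("OK", variogram = vm, window = win),
                     "z")
  # constant data predict the constant wherever defined (weights sum to 1)
  expect_true(all(abs(rI$values[!is.na(rI$values)] - 50) < 1e-9))
  expect_true(all(abs(rO$values[!is.na(rO$values)] - 50) < 1e-8))
  # far cells lack neighbours -> NODATA
  expect_true(any(is.na(rI$values)))
  expect_true(identical(is.na(rI$values), is.na(rO$values)))
  # clamping bounds OK output
  s2 <- toy_samples(20, seed = 20)
  g2 <- grid_spec(0, 0, 10, 10, 10)
  vm2 <- variogram_model("gaussian", 0.01, 2, 50)
  rc <- predict_grid(s2, g2, interp_config("OK", variogram = vm2,
                                           window = full_window(),
                                           clamp_to_range = TRUE), "cover")
  fin <- rc$values[!is.na(rc$values)]
  expect_true(all(fin >= 0 & fin <= 100))
})
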