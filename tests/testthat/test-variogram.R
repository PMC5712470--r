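# Variography: Matheron estimator, model closed forms, WLS fitting.

test_that("Matheron estimator reproduces the hand-enumerated collinear case", {
  s <- structure(data.frame(x = c(0, 5, 10), y = 0, z = c(0, 1, 3)),
                 class = c("reef_samples", "data.frame"), taxa = "z")
  emp <- empirical_variogram(s, "z", lag_width = 5, max_lag = 10)
  expect_equal(emp$lag, c(5, 10))
  # bin [2.5, 7.5): pairs (0,1) and (1,3): (1 + 4) / (2 * 2)
  expect_equal(emp$gamma[1], 1.25)
  expect_equal(emp$n_pairs[1], 2L)
  # bin [7.5, 12.5): pair (0,3): 9 / 2
  expect_equal(emp$gamma[2], 4.5)
  expect_equal(emp$n_pairs[2], 1L)
})

test_that("Matheron estimator equals the all-pairs brute-force oracle", {
  for (seed in c(2, 7, 19)) {
    set.seed(seed)
    n <- sample(10:50, 1)
    x <- runif(n, 0, 60); y <- runif(n, 0, 60)
    z <- runif(n, 0, 100)
    s <- structure(data.frame(x = x, y = y, z = z),
                   class = c("reef_samples", "data.frame"), taxa = "z")
    emp <- empirical_variogram(s, "z", lag_width = 7, max_lag = 49)
    orc <- oracle_matheron(x, y, z, 7, 49)
    expect_equal(emp$gamma, orc$gamma)
    expect_equal(emp$n_pairs, orc$n_pairs)
    # pair-count bound, with equality when max_lag exceeds the diameter
    expect_lte(sum(emp$n_pairs), n * (n - 1) / 2)
    emp_all <- empirical_variogram(s, "z", lag_width = 10, max_lag = 200)
    expect_equal(sum(emp_all$n_pairs), n * (n - 1) / 2)
  }
})

test_that("constant fields and coincident duplicates behave as expected", {
  s <- structure(data.frame(x = c(0, 4, 9, 14), y = 0, z = 5),
                 class = c("reef_samples", "data.frame"), taxa = "z")
  emp <- empirical_variogram(s, "z", lag_width = 5, max_lag = 15)
  expect_true(all(emp$gamma[emp$n_pairs > 0] == 0))

  set.seed(3)
  x <- runif(12, 0, 30); y <- runif(12, 0, 30); z <- runif(12, 0, 50)
  s1 <- structure(data.frame(x = x, y = y, z = z),
                  class = c("reef_samples", "data.frame"), taxa = "z")
  s2 <- structure(data.frame(x = c(x, x), y = c(y, y), z = c(z, z)),
                  class = c("reef_samples", "data.frame"), taxa = "z")
  e1 <- empirical_variogram(s1, "z", lag_width = 6, max_lag = 30)
  e2 <- empirical_variogram(s2, "z", lag_width = 6, max_lag = 30)
  expect_equal(e1$gamma, e2$gamma)   # coincident copies do not bias lags > 0
})

test_that("semivariogram closed forms match direct evaluation", {
  sph <- variogram_model("spherical", nugget = 0, psill = 2, range = 10)
  expect_equal(model_gamma(sph, 0), 0)
  expect_equal(model_gamma(sph, 10), 2)
  expect_equal(model_gamma(sph, 20), 2)
  expect_equal(model_gamma(sph, 5), 2 * (0.75 - 0.0625))
  ex <- variogram_model("exponential", nugget = 1, psill = 4, range = 30)
  expect_equal(model_gamma(ex, 0), 0)
  expect_equal(model_gamma(ex, 30), 1 + 4 * (1 - exp(-3)), tolerance = 1e-12)
  expect_equal(model_gamma(ex, 1e6), 5, tolerance = 1e-9)
  nug <- variogram_model("nugget", nugget = 1.5, psill = 0, range = 1)
  expect_equal(model_gamma(nug, c(0, 0.001, 50)), c(0, 1.5, 1.5))
  expect_error(model_gamma(sph, -1), "non-negative")
  # against the independently coded closed forms, over random parameters
  set.seed(8)
  for (type in c("spherical", "exponential", "gaussian")) {
    c0 <- runif(1, 0, 2); c1 <- runif(1, 0.1, 3); a <- runif(1, 5, 80)
    h <- sort(runif(50, 0, 160))
    m <- variogram_model(type, c0, c1, a)
    expect_equal(model_gamma(m, h), oracle_gamma(type, c0, c1, a, h))
    expect_true(all(diff(model_gamma(m, h)) >= -1e-12))  # monotone in h
  }
})

fake_emp <- function(model, lags, n_pairs = 50) {
  structure(data.frame(lag = lags, gamma = model_gamma(model, lags),
                       n_pairs = n_pairs),
            class = c("empirical_variogram", "data.frame"),
            taxon = "z", lag_width = diff(lags[1:2]), max_lag = max(lags) + 1,
            n = 100)
}

test_that("WLS fit recovers parameters exactly from noiseless model bins", {
  truth <- variogram_model("spherical", nugget = 0, psill = 1, range = 50)
  emp <- fake_emp(truth, seq(2.5, 97.5, by = 5))
  fit <- fit_variogram(emp, "spherical")
  expect_equal(coef(fit), coef(truth), tolerance = 1e-4)
  truth2 <- variogram_model("exponential", nugget = 0.3, psill = 1.7,
                            range = 35)
  fit2 <- fit_variogram(fake_emp(truth2, seq(2.5, 97.5, by = 5)),
                        "exponential")
  expect_equal(coef(fit2), coef(truth2), tolerance = 1e-3)
})

test_that("structureless variograms degrade to flagged degenerate fits", {
  flat <- structure(data.frame(lag = seq(2.5, 47.5, 5), gamma = 2,
                               n_pairs = 30),
                    class = c("empirical_variogram", "data.frame"),
                    taxon = "z", lag_width = 5, max_lag = 50, n = 60)
  fit <- fit_variogram(flat, "spherical")
  expect_true(fit$degenerate || fit$psill < 1e-6 * 2 ||
              fit$nugget / (fit$nugget + fit$psill) > 0.95)
  zero <- flat; zero$gamma <- 0
  expect_warning(fz <- fit_variogram(zero, "spherical"), "zero")
  expect_equal(fz$nugget + fz$psill, 0)
})

test_that("a singleton candidate set is returned without cross-validation", {
  reef <- small_reef(seed = 21)
  got <- select_best_model(reef$samples, "sponges",
                           candidates = "spherical", max_lag = 100)
  direct <- fit_variogram(
    empirical_variogram(reef$samples, "sponges", max_lag = 100), "spherical")
  expect_equal(coef(got), coef(direct))
})

test_that("model selection scores candidates by CV mean error", {
  reef <- small_reef(seed = 22)
  got <- select_best_model(reef$samples, "macroalgae",
                           candidates = c("spherical", "exponential"),
                           max_lag = 100)
  sel <- attr(got, "selection")
  expect_equal(nrow(sel), 2)
  best <- sel[order(sel$ME, -sel$r2, sel$nugget), ][1, ]
  expect_equal(got$model_type, best$model_type)
})
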