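test_that("GWR with a huge bandwidth collapses to global OLS", {
  withr::with_seed(60, {
    n <- 30
    sites <- data.frame(x = runif(n, 0, 1000), y = runif(n, 0, 1000))
    X <- data.frame(a = rnorm(n), b = runif(n))
    y <- 2 + 1.5 * X$a - 3 * X$b + rnorm(n, 0, 0.5)
  })
  g <- fit_gwr(sites, y, X, kernel = "gaussian", bandwidth = 1e8)
  ols <- fit_ols(y, X)
  for (i in seq_len(n)) {
    expect_equal(unname(g$coefficients[i, ]), unname(ols$coefficients),
                 tolerance = 1e-6)
  }
})

test_that("a west-to-east coefficient flip is detected by local fits", {
  withr::with_seed(61, {
    n <- 80
    sites <- data.frame(x = runif(n, 0, 2000), y = runif(n, 0, 2000))
    X <- data.frame(a = rnorm(n))
    beta <- 4 * (1 - sites$x / 1000)       # +4 in the west, -4 in the east
    y <- 1 + beta * X$a + rnorm(n, 0, 0.1)
  })
  g <- fit_gwr(sites, y, X, kernel = "gaussian", bandwidth = 400)
  west <- sites$x < 500; east <- sites$x > 1500
  expect_true(all(g$coefficients[west, "a"] > 0))
  expect_true(all(g$coefficients[east, "a"] < 0))
})

test_that("an infeasibly small bandwidth names the failing site", {
  withr::with_seed(62, {
    sites <- data.frame(x = c(0, 1, 2000, 3000), y = c(0, 1, 2000, 3000))
    X <- data.frame(a = rnorm(4))
    y <- rnorm(4)
  })
  expect_error(fit_gwr(sites, y, X, kernel = "bisquare", bandwidth = 10),
               "site")
})

test_that("bandwidth selection prefers large bandwidths on globally linear data", {
  withr::with_seed(63, {
    n <- 40
    sites <- data.frame(x = runif(n, 0, 2000), y = runif(n, 0, 2000))
    X <- data.frame(a = rnorm(n))
    y <- 3 + 2 * X$a + rnorm(n, 0, 0.1)
  })
  cands <- c(250, 500, 1000, 4000, 16000)
  bw <- select_bandwidth(sites, y, X, kernel = "gaussian", candidates = cands)
  expect_equal(bw, 16000)
  expect_equal(bw, select_bandwidth(sites, y, X, candidates = cands))
  expect_error(select_bandwidth(sites, y, X, candidates = c(100, 200)),
               "3 candidate")
})

test_that("bandwidth selection localises under strong heterogeneity", {
  withr::with_seed(64, {
    n <- 90
    sites <- data.frame(x = runif(n, 0, 2000), y = runif(n, 0, 2000))
    X <- data.frame(a = rnorm(n))
    beta <- 5 * sin(sites$x / 300)
    y <- beta * X$a + rnorm(n, 0, 0.1)
  })
  bw <- select_bandwidth(sites, y, X, kernel = "gaussian",
                         candidates = c(125, 250, 500, 1000, 4000))
  expect_lt(bw, 1000)   # less than extent/2
})

test_that("mesh construction matches the lattice counts", {
  m <- make_mesh(c(0, 0, 1000, 1000), 200)
  expect_equal(nrow(m), 36)
  expect_equal(sort(unique(m$x)), seq(0, 1000, 200))
  m2 <- make_mesh(c(0, 0, 1000, 1000), 1000)
  expect_equal(nrow(m2), 4)
  expect_true(all(m$x >= 0 & m$x <= 1000 & m$y >= 0 & m$y <= 1000))
  expect_warning(make_mesh(c(0, 0, 100, 100), 500), "degenerates")
})

test_that("the thin-plate spline interpolates its knots and behaves between them", {
  withr::with_seed(65, {
    n <- 40
    x <- runif(n, 0, 1000); y <- runif(n, 0, 1000)
    v <- sin(x / 200) + cos(y / 300)
  })
  tps <- fit_tps(x, y, v)
  expect_equal(predict_tps(tps, x, y), v, tolerance = 1e-6)
  # exactly reproduces an affine field everywhere (polynomial part)
  va <- 2 + 0.001 * x - 0.002 * y
  tps_a <- fit_tps(x, y, va)
  gx <- runif(20, 0, 1000); gy <- runif(20, 0, 1000)
  expect_equal(predict_tps(tps_a, gx, gy), 2 + 0.001 * gx - 0.002 * gy,
               tolerance = 1e-6)
})

test_that("surface prediction is flat for an intercept-only model and interpolating", {
  city <- small_city(seed = 66)
  m0 <- lur_model("PM2.5", "identity", 17.5)
  surf <- predict_surface(m0, city, spacing = 500, resolution = 250)
  expect_equal(surf$mesh$value, rep(17.5, nrow(surf$mesh)))
  expect_equal(max(abs(surf$raster$values - 17.5)), 0, tolerance = 1e-6)
  # interpolation property at the mesh points of a non-trivial model
  m1 <- lur_model("PM2.5", "identity", 10,
                  data.frame(predictor = "RES500", coefficient = 8))
  surf1 <- predict_surface(m1, city, spacing = 500, resolution = 250)
  back <- predict_tps(surf1$tps, surf1$mesh$x, surf1$mesh$y)
  expect_equal(back, surf1$mesh$value, tolerance = 1e-6)
  expect_equal(surf1$coef_source, "global")
})

test_that("adding a constant to y shifts identity surfaces by that constant", {
  city <- small_city(seed = 67)
  sites <- generate_sites(city, 12, seed = 68)
  ptab <- build_predictor_table(city, sites, quiet = TRUE)
  withr::with_seed(69, y <- 12 + 5 * ptab$RES500 + rnorm(12, 0, 0.3))
  f1 <- fit_ols(y, ptab["RES500"])
  f2 <- fit_ols(y + 7, ptab["RES500"])
  m1 <- lur_model("PM2.5", "identity", f1$coefficients[1],
                  data.frame(predictor = "RES500",
                             coefficient = f1$coefficients[2]))
  m2 <- lur_model("PM2.5", "identity", f2$coefficients[1],
                  data.frame(predictor = "RES500",
                             coefficient = f2$coefficients[2]))
  s1 <- predict_surface(m1, city, spacing = 500, resolution = 500)
  s2 <- predict_surface(m2, city, spacing = 500, resolution = 500)
  expect_equal(s2$raster$values, s1$raster$values + 7, tolerance = 1e-8)
})

test_that("GWR surfaces use kernel-weighted local calibration at mesh points", {
  city <- small_city(seed = 70)
  sites <- generate_sites(city, 15, seed = 71)
  ptab <- build_predictor_table(city, sites, quiet = TRUE)
  withr::with_seed(72, y <- 10 + 6 * ptab$RES500 + rnorm(15, 0, 0.2))
  g <- fit_gwr(sites, y, ptab["RES500"], bandwidth = 1e7)
  surf <- predict_surface(g, city, spacing = 500, resolution = 500)
  expect_equal(surf$coef_source, "gwr-local")
  # flat-kernel limit: the GWR surface equals the global-model surface
  ols <- fit_ols(y, ptab["RES500"])
  mg <- lur_model("PM2.5", "identity", ols$coefficients[1],
                  data.frame(predictor = "RES500",
                             coefficient = ols$coefficients[2]))
  s2 <- predict_surface(mg, city, spacing = 500, resolution = 500)
  expect_equal(surf$mesh$value, s2$mesh$value, tolerance = 1e-5)
})
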