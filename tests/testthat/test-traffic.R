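test_that("noise-free Greenshields data are recovered exactly", {
  obs <- simulate_flow_observations("greenshields", c(vf = 60, kj = 120),
                                    n = 50, noise_sd = 0, seed = 1)
  m <- fit_flow_model(obs, n_resamples = 25, seed = 2)
  expect_equal(m$form, "greenshields")
  expect_lt(abs(m$parameters[["vf"]] - 60) / 60, 0.01)
  expect_lt(abs(m$parameters[["kj"]] - 120) / 120, 0.01)
  expect_lt(m$rmse, 1e-6)
})

test_that("each form is self-consistent: exact data, exact refit", {
  pars <- list(greenshields = c(vf = 60, kj = 120),
               greenberg = c(v0 = 25, kj = 150),
               underwood = c(vf = 70, k0 = 50),
               pipes = c(vf = 55, kj = 110),
               drew = c(vf = 65, kj = 130),
               may_keller = c(vf = 60, kj = 120, a = 2))
  for (form in names(pars)) {
    obs <- simulate_flow_observations(form, pars[[form]], n = 60,
                                      noise_sd = 0, seed = 3)
    m <- suppressWarnings(fit_flow_model(obs, forms = form,
                                         n_resamples = 10, seed = 4))
    expect_lt(m$rmse, 1e-6)
    vhat <- flow_speed(m, obs$density)
    expect_equal(vhat, obs$speed, tolerance = 1e-6)
  }
})

test_that("degenerate and invalid observations are refused", {
  one <- data.frame(density = rep(30, 20), speed = rep(40, 20))
  expect_error(fit_flow_model(one), "degenerate")
  few <- data.frame(density = 1:5, speed = 5:1)
  expect_error(fit_flow_model(few), "at least 10")
  neg <- data.frame(density = c(-1, 1:19), speed = 19:0)
  expect_error(fit_flow_model(neg), "positive")
})

test_that("fitting is deterministic for a fixed seed", {
  obs <- simulate_flow_observations("underwood", c(vf = 70, k0 = 50),
                                    n = 80, noise_sd = 2, seed = 5)
  m1 <- suppressWarnings(fit_flow_model(obs, n_resamples = 25, seed = 6))
  m2 <- suppressWarnings(fit_flow_model(obs, n_resamples = 25, seed = 6))
  expect_identical(m1, m2)
})

test_that("volume estimation follows the fundamental-diagram closed forms", {
  gs <- structure(list(form = "greenshields",
                       parameters = c(vf = 60, kj = 120),
                       regime = "uninterrupted"), class = "flow_model")
  # free-flow limit: zero density, zero flow
  expect_equal(estimate_volume(gs, 60), 0)
  # capacity: at v = vf/2, q = vf * kj / 4 per lane
  expect_equal(estimate_volume(gs, 30), 60 * 120 / 4)
  # linear in lanes
  expect_equal(estimate_volume(gs, 45, lanes = 3),
               3 * estimate_volume(gs, 45, lanes = 1))
  expect_error(estimate_volume(gs, 61), "free-flow")
  expect_error(estimate_volume(gs, -5), "positive")
  # inversion consistency across forms: q(v(k)) = k * v(k)
  pars <- list(greenshields = c(vf = 60, kj = 120),
               greenberg = c(v0 = 25, kj = 150),
               underwood = c(vf = 70, k0 = 50),
               pipes = c(vf = 55, kj = 110),
               drew = c(vf = 65, kj = 130),
               may_keller = c(vf = 60, kj = 120, a = 2))
  for (form in names(pars)) {
    m <- structure(list(form = form, parameters = pars[[form]],
                        regime = "interrupted"), class = "flow_model")
    k <- c(5, 20, 40)
    v <- flow_speed(m, k)
    expect_equal(estimate_volume(m, v), k * v, tolerance = 1e-8)
  }
})

test_that("flow curves are physical: v non-increasing, q -> 0 at free flow", {
  pars <- list(greenshields = c(vf = 60, kj = 120),
               greenberg = c(v0 = 25, kj = 150),
               underwood = c(vf = 70, k0 = 50),
               pipes = c(vf = 55, kj = 110),
               drew = c(vf = 65, kj = 130),
               may_keller = c(vf = 60, kj = 120, a = 2))
  for (form in names(pars)) {
    m <- list(form = form, parameters = pars[[form]])
    kmax <- if ("kj" %in% names(pars[[form]])) pars[[form]][["kj"]] else 200
    k <- seq(kmax * 1e-4, kmax * 0.99, length.out = 200)
    v <- flow_speed(m, k)
    expect_true(all(diff(v) <= 1e-9), label = paste(form, "monotone"))
    k0 <- kmax * 1e-8
    expect_lt(k0 * flow_speed(m, k0), 0.01)   # q -> 0 as k -> 0+
  }
  # Greenshields flow is concave in k with maximum vf*kj/4 at k = kj/2
  gs <- list(form = "greenshields", parameters = c(vf = 60, kj = 120))
  k <- seq(0, 120, by = 0.5)
  q <- k * flow_speed(gs, k)
  expect_equal(max(q), 60 * 120 / 4, tolerance = 1e-9)
  expect_equal(k[which.max(q)], 60)
  expect_true(all(diff(q, differences = 2) <= 1e-6))
})

test_that("road attribution produces positive speeds and volumes per class", {
  city <- small_city(seed = 30)
  roads <- assign_road_traffic(city, seed = 31)
  expect_true(all(roads$speed > 0))
  expect_true(all(roads$volume >= 0))
  expect_true(all(roads$regime %in%
                    c("interrupted", "semi-interrupted", "uninterrupted")))
  # same seed reproduces the attribution
  expect_identical(roads, assign_road_traffic(city, seed = 31))
})
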