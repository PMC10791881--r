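test_that("land-use fractions handle saturated, empty and half-plane buffers", {
  hp <- halfplane_city(split = 0)
  # deep inside the IND half-plane
  expect_equal(landuse_fraction(hp, -3000, 0, 100, "IND"), 1, tolerance = 1e-9)
  # farther than r from any IND polygon
  expect_equal(landuse_fraction(hp, 3000, 0, 500, "IND"), 0)
  # boundary through the site: exactly half
  expect_equal(landuse_fraction(hp, 0, 0, 100, "IND"), 0.5, tolerance = 1e-6)
  expect_equal(landuse_fraction(hp, 0, 0, 500, "RES"), 0.5, tolerance = 1e-6)
})

test_that("geographic-degree layers are rejected", {
  hp <- halfplane_city()
  hp$crs <- "EPSG:4326"
  expect_error(landuse_fraction(hp, 0, 0, 100, "IND"), "metric CRS")
})

test_that("road length in buffer follows chord geometry", {
  roads <- data.frame(class = c("PRIM", "SEC"),
                      x1 = c(-1000, -1000), y1 = c(0, 300),
                      x2 = c(1000, 1000), y2 = c(0, 300))
  expect_equal(road_length_in_buffer(roads, 0, 0, 500, "PRIM"), 1000)
  expect_equal(road_length_in_buffer(roads, 0, 0, 500, "SEC"),
               2 * sqrt(500^2 - 300^2), tolerance = 1e-9)
  expect_equal(road_length_in_buffer(roads, 0, 0, 500, "LOC"), 0)
  expect_error(road_length_in_buffer(roads, 0, 0, 500, "FREEWAY"),
               "unknown road class")
})

test_that("distance to road matches a brute-force oracle on random layouts", {
  withr::with_seed(21, {
    roads <- data.frame(class = "TER",
                        x1 = runif(30, 0, 2000), y1 = runif(30, 0, 2000),
                        x2 = runif(30, 0, 2000), y2 = runif(30, 0, 2000))
    px <- runif(50, 0, 2000); py <- runif(50, 0, 2000)
  })
  brute <- function(x, y) {
    best <- Inf
    for (i in seq_len(nrow(roads))) {
      # exhaustive over segments; 1-D minimisation along each one
      f <- function(t) {
        qx <- roads$x1[i] + t * (roads$x2[i] - roads$x1[i])
        qy <- roads$y1[i] + t * (roads$y2[i] - roads$y1[i])
        sqrt((x - qx)^2 + (y - qy)^2)
      }
      best <- min(best, f(0), f(1), optimize(f, c(0, 1), tol = 1e-10)$objective)
    }
    best
  }
  for (i in seq_along(px)) {
    expect_equal(distance_to_road(roads, px[i], py[i], "TER"),
                 brute(px[i], py[i]), tolerance = 1e-8)
  }
})

test_that("distance to an absent class is an NA sentinel with a warning", {
  roads <- data.frame(class = "TER", x1 = 0, y1 = 0, x2 = 1, y2 = 1)
  expect_warning(d <- distance_to_road(roads, 5, 5, "TRUNK"), "TRUNK")
  expect_true(is.na(d))
  expect_equal(distance_to_road(roads, 0, 0, "TER"), 0)
})

test_that("population in buffer integrates a uniform density exactly", {
  pop <- uniform_pop(density = 0.01, cellsize = 25)
  for (r in c(100, 200, 500)) {
    pb <- population_in_buffer(pop, 1000, 1000, r)
    expect_equal(unname(pb["POB"]), 0.01 * pi * r^2, tolerance = 1e-6)
    # definitional identity DEN * pi r^2 = POB
    expect_equal(unname(pb["DEN"] * pi * r^2), unname(pb["POB"]),
                 tolerance = 1e-12)
  }
  zero <- lur_raster(matrix(0, 40, 40), 0, 0, 50)
  expect_equal(unname(population_in_buffer(zero, 1000, 1000, 200)),
               c(0, 0))
  expect_error(population_in_buffer(pop, 50, 50, 500), "allow_partial")
})

test_that("the full predictor table matches the catalogue and per-op recomputation", {
  city <- small_city(seed = 12)
  sites <- generate_sites(city, 8, seed = 13)
  traffic <- assign_road_traffic(city, seed = 14)
  met <- build_met_surfaces(city)
  tab <- build_predictor_table(city, sites, traffic = traffic, met = met,
                               quiet = TRUE)
  cat_full <- predictor_catalogue()
  expect_equal(nrow(cat_full), 69)
  expect_setequal(setdiff(names(tab), "site_id"), cat_full$name)
  expect_named(attr(tab, "units"))
  # spot-check every column family against a single-site recomputation
  i <- 3
  expect_equal(tab$IND200[i],
               landuse_fraction(city, sites$x[i], sites$y[i], 200, "IND"))
  expect_equal(tab$SEC100[i],
               road_length_in_buffer(city$roads, sites$x[i], sites$y[i],
                                     100, "SEC"))
  expect_equal(tab$DLOC500[i],
               suppressWarnings(distance_to_road(city$roads, sites$x[i],
                                                 sites$y[i], "LOC")))
  pb <- population_in_buffer(city$population, sites$x[i], sites$y[i], 500)
  expect_equal(tab$POB500[i], unname(pb["POB"]))
  expect_equal(tab$DEN500[i], unname(pb["DEN"]))
  expect_equal(tab$ALT[i],
               raster_value_at(city$altitude, sites$x[i], sites$y[i]))
})

test_that("omitted met layers omit the met columns with a message", {
  city <- small_city(seed = 15)
  sites <- generate_sites(city, 5, seed = 16)
  expect_message(tab <- build_predictor_table(city, sites),
                 "meteorological")
  expect_false(any(c("TPROM", "PPROM", "HR", "WD", "WPROM") %in% names(tab)))
  expect_false(any(c("VEL100", "VOL500") %in% names(tab)))
})

test_that("duplicate site ids are rejected", {
  city <- small_city(seed = 17)
  sites <- generate_sites(city, 5, seed = 18)
  sites$site_id[2] <- sites$site_id[1]
  expect_error(build_predictor_table(city, sites, quiet = TRUE), "duplicate")
})

test_that("road length and population are monotone in the buffer radius", {
  city <- small_city(seed = 19)
  sites <- generate_sites(city, 6, seed = 20)
  tab <- build_predictor_table(city, sites, quiet = TRUE)
  for (cl in c("TRUNK", "PRIM", "SEC", "TER", "LOC")) {
    expect_true(all(tab[[paste0(cl, 100)]] <= tab[[paste0(cl, 200)]] + 1e-9))
    expect_true(all(tab[[paste0(cl, 200)]] <= tab[[paste0(cl, 500)]] + 1e-9))
  }
  expect_true(all(tab$POB100 <= tab$POB200 + 1e-9))
  expect_true(all(tab$POB200 <= tab$POB500 + 1e-9))
})

test_that("predictors are invariant under a rigid translation of the scene", {
  hp <- halfplane_city(split = 200)
  roads <- data.frame(class = "PRIM", x1 = -1000, y1 = 100, x2 = 1000,
                      y2 = 100)
  shift <- c(12345.6, -987.3)
  hp2 <- hp
  hp2$landuse <- lapply(hp$landuse, function(p) {
    p$xy <- sweep(p$xy, 2, -shift); p
  })
  roads2 <- transform(roads, x1 = x1 + shift[1], x2 = x2 + shift[1],
                      y1 = y1 + shift[2], y2 = y2 + shift[2])
  for (r in c(100, 500)) {
    expect_equal(landuse_fraction(hp, 50, 0, r, "IND"),
                 landuse_fraction(hp2, 50 + shift[1], 0 + shift[2], r, "IND"),
                 tolerance = 1e-9)
    expect_equal(road_length_in_buffer(roads, 0, 0, r, "PRIM"),
                 road_length_in_buffer(roads2, shift[1], shift[2], r, "PRIM"),
                 tolerance = 1e-9)
  }
  expect_equal(distance_to_road(roads, 0, 0, "PRIM"),
               distance_to_road(roads2, shift[1], shift[2], "PRIM"),
               tolerance = 1e-9)
})

test_that("every catalogue predictor matches exactly one sign pattern", {
  signs <- expected_signs()
  for (nm in predictor_catalogue()$name) {
    hits <- sum(vapply(signs$pattern, function(p) grepl(p, nm), TRUE))
    expect_equal(hits, 1L, label = paste("patterns matching", nm))
  }
  expect_equal(unname(sign_for(c("ALT", "DTRON500", "SEC100", "VOL200"))),
               c("-", "-", "+", "+"))
})
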