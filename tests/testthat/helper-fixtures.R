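# small fixtures shared across tests; everything is generated in code

# a compact city for fast tests (still >= 1 km^2 with 500 m buffers inside)
small_city <- function(seed = 11) {
  generate_city(extent = c(0, 0, 2000, 2000), n_blobs = 20,
                road_spacing = 250, cellsize = 50, n_met = 8, seed = seed)
}

# half-plane land-use layer: IND for x <= split, RES beyond, over a big box
halfplane_city <- function(split = 0, span = 10000) {
  list(crs = "local-metric",
       extent = c(-span, -span, span, span),
       landuse = list(
         list(category = "IND",
              xy = rbind(c(-span, -span), c(split, -span),
                         c(split, span), c(-span, span))),
         list(category = "RES",
              xy = rbind(c(split, -span), c(span, -span),
                         c(span, span), c(split, span)))))
}

# uniform-density population raster (persons per cell)
uniform_pop <- function(density = 0.01, cellsize = 25, span = 2000) {
  n <- span / cellsize
  lur_raster(matrix(density * cellsize^2, n, n), 0, 0, cellsize)
}

expect_close <- function(object, expected, tol = 1e-8) {
  expect_true(all(abs(object - expected) <= tol),
              label = sprintf("%s within %g of %s",
                              deparse(substitute(object)), tol,
                              deparse(substitute(expected))))
}
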