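#' Seeded synthetic cities with known ground truth
#'
#' Real campaign measurements and municipal GIS layers for LUR studies are
#' rarely redistributable, so the package carries a generator that emulates
#' their structure: a projected-metric extent partitioned into categorical
#' land-use polygons, a classed road grid, population and altitude rasters,
#' and a small meteorological station network. Because the concentration
#' field is generated from a known linear model plus Gaussian noise
#' (epsilon ~ N(0, v^2)), every downstream stage -- buffer extraction,
#' screening, selection, GWR, LOOCV -- can be verified by parameter recovery.
#'
#' @name synthcity
NULL

.LANDUSE_CATEGORIES <- c("IND", "RES", "DOT", "CEN", "COM", "PORT", "MIX")
.ROAD_CLASSES <- c("TRUNK", "PRIM", "SEC", "TER", "LOC")
.ROAD_LANES <- c(TRUNK = 4L, PRIM = 3L, SEC = 2L, TER = 2L, LOC = 1L)

# category weights: residential dominates, port is rare (coastal cities only)
.LANDUSE_WEIGHTS <- c(IND = 0.10, RES = 0.40, DOT = 0.08, CEN = 0.08,
                      COM = 0.12, PORT = 0.05, MIX = 0.17)

# persons per square metre by land use (12,000 / km^2 in residential blocks)
.POP_DENSITY <- c(IND = 0.001, RES = 0.012, DOT = 0.004, CEN = 0.015,
                  COM = 0.008, PORT = 0.0005, MIX = 0.010)

# Voronoi cell of seed i within the extent rectangle, by clipping the
# rectangle with the perpendicular-bisector half-plane against every other
# seed.  Cells are convex and partition the extent exactly.
.voronoi_cell <- function(seeds, i, extent) {
  poly <- rbind(c(extent[1], extent[2]), c(extent[3], extent[2]),
                c(extent[3], extent[4]), c(extent[1], extent[4]))
  p <- seeds[i, ]
  for (j in seq_len(nrow(seeds))) {
    if (j == i) next
    q <- seeds[j, ]
    d <- q - p
    cc <- sum(q * q - p * p) / 2
    poly <- clip_halfplane(poly, d[1], d[2], cc)
    if (nrow(poly) < 3) break
  }
  poly
}

# smooth random field over points: sum of seeded cosine modes with
# wavelengths between cycles[1] and cycles[2] per extent span
.smooth_field <- function(x, y, extent, n_modes = 4, amplitude = 1,
                          cycles = c(0.5, 2.5)) {
  lx <- extent[3] - extent[1]; ly <- extent[4] - extent[2]
  z <- numeric(length(x))
  for (m in seq_len(n_modes)) {
    fx <- stats::runif(1, cycles[1], cycles[2]) / lx
    fy <- stats::runif(1, cycles[1], cycles[2]) / ly
    ph <- stats::runif(2, 0, 2 * pi)
    z <- z + stats::runif(1, 0.3, 1) *
      cos(2 * pi * fx * (x - extent[1]) + ph[1]) *
      cos(2 * pi * fy * (y - extent[2]) + ph[2])
  }
  amplitude * z / sqrt(n_modes)
}

#' Generate a synthetic city
#'
#' Land use is a Voronoi partition of seeded points with categories drawn
#' from a fixed urban mix; roads are a jittered grid in which trunk and
#' primary corridors sit on the coarse lattice tiers (every 8th and 4th
#' line) and the remaining lines are split into short segments with
#' secondary/tertiary/local class drawn per segment; population density
#' follows land use modulated by a block-scale random field; altitude is
#' a smooth long-wavelength surface; meteorological stations observe
#' temperature (with a lapse rate on altitude), precipitation, humidity,
#' wind direction and mean wind speed.
#'
#' @param extent numeric c(xmin, ymin, xmax, ymax) in metres. Must span at
#'   least 1000 m per side (twice the largest 500 m buffer radius) and
#'   cover at least 1 km^2.
#' @param n_blobs number of land-use Voronoi seeds; 0 gives a single
#'   residential polygon covering the extent.
#' @param road_spacing grid spacing between road centrelines (m).
#' @param cellsize raster cell size (m) for population and altitude.
#' @param n_met number of meteorological stations.
#' @param alt_base,alt_relief base altitude and relief amplitude (m).
#' @param seed integer seed; all randomness flows from it and global RNG
#'   state is untouched.
#' @return A \code{lur_city}: list with \code{extent}, \code{landuse}
#'   (list of \code{category} + vertex matrix), \code{landuse_seeds},
#'   \code{roads} (data frame of classed segments with lanes),
#'   \code{population} and \code{altitude} rasters, and
#'   \code{met_stations}.
#' @export
generate_city <- function(extent = c(0, 0, 7000, 7000), n_blobs = 220,
                          road_spacing = 250, cellsize = 50, n_met = 6,
                          alt_base = 1000, alt_relief = 50, seed = 1) {
  stopifnot(length(extent) == 4, extent[3] > extent[1], extent[4] > extent[2])
  w <- extent[3] - extent[1]; h <- extent[4] - extent[2]
  if (w * h < 1e6 || w < 1000 || h < 1000) {
    stop("extent must cover at least 1 km^2 and span >= 1000 m per side ",
         "(500 m buffers must fit)")
  }
  withr::with_seed(seed, {
    # --- land use -----------------------------------------------------
    if (n_blobs == 0) {
      seeds <- matrix(c(mean(extent[c(1, 3)]), mean(extent[c(2, 4)])), ncol = 2)
      cats <- "RES"
    } else {
      seeds <- cbind(stats::runif(n_blobs, extent[1], extent[3]),
                     stats::runif(n_blobs, extent[2], extent[4]))
      cats <- sample(names(.LANDUSE_WEIGHTS), n_blobs, replace = TRUE,
                     prob = .LANDUSE_WEIGHTS)
    }
    landuse <- lapply(seq_len(nrow(seeds)), function(i) {
      xy <- .voronoi_cell(seeds, i, extent)
      list(category = cats[i], xy = xy,
           bbox = c(range(xy[, 1]), range(xy[, 2])))
    })

    # --- roads --------------------------------------------------------
    nv <- max(floor(w / road_spacing) - 1L, 0L)
    nh <- max(floor(h / road_spacing) - 1L, 0L)
    jit <- function(n) stats::runif(n, -0.15, 0.15) * road_spacing
    # major lines (trunk/primary on the coarse lattice tiers) run whole
    # corridors; minor lines are split into ~2-spacing segments whose
    # class is drawn per segment, as street class changes along real
    # corridors (and whole-line classes would correlate buffers citywide)
    line_segments <- function(k, pos, lo, hi, vertical) {
      major <- if (k %% 8 == 0) "TRUNK" else if (k %% 4 == 0) "PRIM" else NA
      if (!is.na(major)) {
        cls <- major
        breaks <- c(lo, hi)
      } else {
        n_seg <- max(ceiling((hi - lo) / (2 * road_spacing)), 1L)
        breaks <- seq(lo, hi, length.out = n_seg + 1L)
        cls <- sample(c("SEC", "TER", "LOC"), n_seg, replace = TRUE,
                      prob = c(0.35, 0.3, 0.35))
      }
      a <- breaks[-length(breaks)]; b <- breaks[-1]
      if (vertical) {
        data.frame(class = cls, x1 = pos, y1 = a, x2 = pos, y2 = b)
      } else {
        data.frame(class = cls, x1 = a, y1 = pos, x2 = b, y2 = pos)
      }
    }
    roads <- list()
    if (nv > 0) {
      xs <- extent[1] + seq_len(nv) * road_spacing + jit(nv)
      roads <- c(roads, lapply(seq_len(nv), function(k) {
        line_segments(k, xs[k], extent[2], extent[4], vertical = TRUE)
      }))
    }
    if (nh > 0) {
      ys <- extent[2] + seq_len(nh) * road_spacing + jit(nh)
      roads <- c(roads, lapply(seq_len(nh), function(k) {
        line_segments(k + 1L, ys[k], extent[1], extent[3], vertical = FALSE)
      }))
    }
    roads <- if (length(roads)) do.call(rbind, roads) else NULL
    if (is.null(roads)) {
      roads <- data.frame(class = character(0), x1 = numeric(0),
                          y1 = numeric(0), x2 = numeric(0), y2 = numeric(0))
    }
    roads$lanes <- unname(.ROAD_LANES[roads$class])
    roads$road_id <- seq_len(nrow(roads))
    roads <- roads[, c("road_id", "class", "lanes", "x1", "y1", "x2", "y2")]

    # --- rasters ------------------------------------------------------
    ncx <- ceiling(w / cellsize); ncy <- ceiling(h / cellsize)
    cxs <- extent[1] + (seq_len(ncx) - 0.5) * cellsize
    cys <- extent[2] + (seq_len(ncy) - 0.5) * cellsize
    gx <- rep(cxs, each = ncy); gy <- rep(cys, times = ncx)
    # nearest land-use seed gives the category of each cell centre
    d2 <- outer(gx, seeds[, 1], "-")^2 + outer(gy, seeds[, 2], "-")^2
    nearest <- max.col(-d2, ties.method = "first")
    base_den <- unname(.POP_DENSITY[cats[nearest]])
    mod <- exp(.smooth_field(gx, gy, extent, n_modes = 6, amplitude = 2,
                               cycles = c(3, 9)))
    pop_density <- base_den * mod
    pop <- lur_raster(matrix(pop_density * cellsize^2, nrow = ncy, ncol = ncx),
                      xmin = extent[1], ymin = extent[2], cellsize = cellsize)

    tilt <- stats::runif(2, -0.01, 0.01)
    altv <- alt_base + tilt[1] * (gx - extent[1]) + tilt[2] * (gy - extent[2]) +
      .smooth_field(gx, gy, extent, amplitude = alt_relief)
    alt <- lur_raster(matrix(altv, nrow = ncy, ncol = ncx),
                      xmin = extent[1], ymin = extent[2], cellsize = cellsize)

    # --- meteorological stations -------------------------------------
    sx <- stats::runif(n_met, extent[1] + 100, extent[3] - 100)
    sy <- stats::runif(n_met, extent[2] + 100, extent[4] - 100)
    salt <- raster_value_at(alt, sx, sy)
    met <- data.frame(
      station_id = paste0("MET", seq_len(n_met)),
      x = sx, y = sy, alt = salt,
      TPROM = 28 - 0.0065 * (salt - alt_base) + stats::rnorm(n_met, 0, 0.3),
      PPROM = pmax(3 + 0.004 * (salt - alt_base) + stats::rnorm(n_met, 0, 0.5), 0.1),
      HR = pmin(pmax(70 + stats::rnorm(n_met, 0, 5), 5), 100),
      WD = stats::runif(n_met, 0, 360),
      WPROM = pmax(2 + stats::rnorm(n_met, 0, 0.5), 0.2))

    structure(list(extent = extent, crs = "local-metric",
                   landuse = landuse,
                   landuse_seeds = data.frame(x = seeds[, 1], y = seeds[, 2],
                                              category = cats),
                   roads = roads, population = pop, altitude = alt,
                   met_stations = met,
                   config = list(extent = extent, n_blobs = n_blobs,
                                 road_spacing = road_spacing,
                                 cellsize = cellsize, n_met = n_met,
                                 alt_base = alt_base, alt_relief = alt_relief,
                                 seed = seed)),
              class = "lur_city")
  })
}

#' @export
print.lur_city <- function(x, ...) {
  cat(sprintf("<lur_city> %g x %g m, %d land-use polygons, %d roads, %d met stations\n",
              x$extent[3] - x$extent[1], x$extent[4] - x$extent[2],
              length(x$landuse), nrow(x$roads), nrow(x$met_stations)))
  invisible(x)
}

#' Land-use category at a point (nearest Voronoi seed)
#'
#' @param city a \code{lur_city}.
#' @param x,y point coordinates (vectors).
#' @return Character vector of categories.
#' @export
landuse_at <- function(city, x, y) {
  s <- city$landuse_seeds
  vapply(seq_along(x), function(i) {
    s$category[which.min((s$x - x[i])^2 + (s$y - y[i])^2)]
  }, "")
}

#' Place monitoring sites stratified by site character
#'
#' Mirrors typical LUR campaign design: sites are spread one-per-cell over
#' a spatial lattice covering the samplable area (campaigns space their
#' monitors to cover the city), with traffic sites snapped to the nearest
#' primary/trunk road with a 10-30 m setback, residential and industrial
#' sites inside the matching land use, and exactly one urban background
#' site placed at the candidate point farthest from major roads.
#'
#' @param city a \code{lur_city}.
#' @param n_sites total number of sites (>= 4). Default 20 matches a
#'   PM2.5-style campaign; use 40 for an NO2-style campaign.
#' @param buffer_margin inset (m) from the extent boundary so the largest
#'   buffer around any site stays inside the city layers.
#' @param seed integer seed.
#' @return Data frame \code{site_id, x, y, stratum} with stratum in
#'   traffic/residential/industrial/background.
#' @export
generate_sites <- function(city, n_sites = 20, buffer_margin = 500,
                           seed = 1) {
  stopifnot(n_sites >= 4)
  ext <- city$extent
  inset <- buffer_margin
  if (ext[3] - ext[1] <= 2 * inset || ext[4] - ext[2] <= 2 * inset) {
    stop("extent too small for the requested buffer margin")
  }
  lo <- c(ext[1] + inset, ext[2] + inset)
  hi <- c(ext[3] - inset, ext[4] - inset)
  withr::with_seed(seed, {
    n_traffic <- max(round(0.40 * (n_sites - 1)), 1)
    n_indus <- max(round(0.20 * (n_sites - 1)), 1)
    n_resid <- n_sites - 1 - n_traffic - n_indus

    major <- city$roads[city$roads$class %in% c("TRUNK", "PRIM"), ]
    if (nrow(major) == 0) major <- city$roads

    # spatially balanced design: one site per cell of a k x k lattice
    # over the samplable area, as campaigns spread monitors to cover the
    # city rather than cluster them
    k <- ceiling(sqrt(n_sites))
    cells <- sample(k * k, n_sites)
    cw <- (hi - lo) / k
    cell_pt <- function(cell) {
      ci <- (cell - 1) %% k; cj <- (cell - 1) %/% k
      lo + c(ci + stats::runif(1, 0.1, 0.9),
             cj + stats::runif(1, 0.1, 0.9)) * cw
    }
    base <- t(vapply(cells, cell_pt, numeric(2)))

    strata <- sample(c(rep("traffic", n_traffic),
                       rep("residential", n_resid),
                       rep("industrial", n_indus), "background"))
    clamp <- function(p) pmin(pmax(p, lo), hi)
    place <- function(i) {
      p <- base[i, ]
      st <- strata[i]
      if (st == "traffic") {
        # snap to the nearest major road, then a 10-30 m setback
        d <- point_segment_distance(p[1], p[2], major$x1, major$y1,
                                    major$x2, major$y2)
        r <- major[which.min(d), ]
        dx <- r$x2 - r$x1; dy <- r$y2 - r$y1
        t <- ((p[1] - r$x1) * dx + (p[2] - r$y1) * dy) / (dx^2 + dy^2)
        t <- min(max(t, 0), 1)
        q <- c(r$x1 + t * dx, r$y1 + t * dy)
        ang <- stats::runif(1, 0, 2 * pi)
        return(clamp(q + stats::runif(1, 10, 30) * c(cos(ang), sin(ang))))
      }
      if (st %in% c("residential", "industrial")) {
        want <- if (st == "residential") c("RES", "MIX") else
          c("IND", "PORT", "COM")
        cell <- cells[i]
        for (try in 1:30) {
          if (landuse_at(city, p[1], p[2]) %in% want) return(p)
          p <- cell_pt(cell)
        }
        return(p)
      }
      # background: the candidate point farthest from major roads
      cand <- rbind(p, t(vapply(rep(cells[i], 30), cell_pt, numeric(2))))
      dmaj <- vapply(seq_len(nrow(cand)), function(j) {
        min(point_segment_distance(cand[j, 1], cand[j, 2], major$x1,
                                   major$y1, major$x2, major$y2))
      }, 0)
      cand[which.max(dmaj), ]
    }
    xy <- t(vapply(seq_len(n_sites), place, numeric(2)))
    data.frame(site_id = sprintf("S%02d", seq_len(n_sites)),
               x = xy[, 1], y = xy[, 2], stratum = strata,
               stringsAsFactors = FALSE)
  })
}

#' Ground-truth concentration field
#'
#' Couples the generating LUR model with the weekly measurement noise SD,
#' following the error model epsilon ~ N(0, v^2).
#'
#' @param true_model a \code{lur_model} whose terms reference predictors
#'   computable from a city.
#' @param noise_sd weekly measurement noise SD (concentration units, >= 0).
#' @return A \code{ground_truth_field}.
#' @export
ground_truth_field <- function(true_model, noise_sd = 0) {
  stopifnot(inherits(true_model, "lur_model"), noise_sd >= 0)
  structure(list(true_model = true_model, noise_sd = noise_sd),
            class = "ground_truth_field")
}

#' Simulate two-campaign weekly measurements at monitoring sites
#'
#' Each site is measured for two weeks in each of a dry and a rainy
#' campaign. Weekly value = true-model prediction + campaign offset +
#' N(0, noise_sd). With symmetric offsets (+d, -d) the expected annual
#' mean equals the true prediction, and dry-season means exceed rainy ones.
#'
#' @param city a \code{lur_city}.
#' @param truth a \code{ground_truth_field}.
#' @param sites site data frame from \code{\link{generate_sites}}.
#' @param campaign_offsets numeric c(dry, rainy) concentration offsets.
#' @param seed integer seed.
#' @param pollutant label stored in the table.
#' @param predictors optional precomputed predictor table for the sites
#'   (saves recomputation in replicate studies).
#' @return Measurement table: \code{site_id, x, y, pollutant, campaign,
#'   week, value}; the true site predictions are attached as attribute
#'   \code{"truth"}.
#' @export
simulate_measurements <- function(city, truth, sites,
                                  campaign_offsets = c(dry = 2, rainy = -2),
                                  seed = 1, pollutant = "PM2.5",
                                  predictors = NULL) {
  stopifnot(inherits(truth, "ground_truth_field"))
  if (is.null(predictors)) {
    need <- truth$true_model$terms$predictor
    predictors <- build_predictor_table(city, sites, quiet = TRUE)
    missing <- setdiff(need, names(predictors))
    if (length(missing) > 0) {
      stop("true model references predictors absent from the city: ",
           paste(missing, collapse = ", "))
    }
  }
  mu <- predict(truth$true_model, predictors)
  n <- nrow(sites)
  withr::with_seed(seed, {
    rows <- lapply(c("dry", "rainy"), function(camp) {
      off <- campaign_offsets[[if (camp == "dry") 1 else 2]]
      do.call(rbind, lapply(1:2, function(wk) {
        data.frame(site_id = sites$site_id, x = sites$x, y = sites$y,
                   pollutant = pollutant, campaign = camp, week = wk,
                   value = mu + off + stats::rnorm(n, 0, truth$noise_sd),
                   stringsAsFactors = FALSE)
      }))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- stats::setNames(mu, sites$site_id)
    out
  })
}

#' Write city layers to plain-text GIS formats
#'
#' Land use, roads and met stations go to GeoJSON (one file per layer);
#' population and altitude to ESRI ASCII grids; the generating config to
#' JSON.
#'
#' @param city a \code{lur_city}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_city <- function(city, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ring <- function(xy) {
    xy <- rbind(xy, xy[1, ])
    lapply(seq_len(nrow(xy)), function(i) c(xy[i, 1], xy[i, 2]))
  }
  lu <- list(type = "FeatureCollection", features = lapply(city$landuse, function(p) {
    list(type = "Feature",
         properties = list(category = p$category),
         geometry = list(type = "Polygon", coordinates = list(ring(p$xy))))
  }))
  rd <- list(type = "FeatureCollection", features = lapply(
    seq_len(nrow(city$roads)), function(i) {
      r <- city$roads[i, ]
      list(type = "Feature",
           properties = list(road_id = r$road_id, class = r$class,
                             lanes = r$lanes),
           geometry = list(type = "LineString",
                           coordinates = list(c(r$x1, r$y1), c(r$x2, r$y2))))
    }))
  ms <- list(type = "FeatureCollection", features = lapply(
    seq_len(nrow(city$met_stations)), function(i) {
      s <- city$met_stations[i, ]
      list(type = "Feature",
           properties = as.list(s[setdiff(names(s), c("x", "y"))]),
           geometry = list(type = "Point", coordinates = c(s$x, s$y)))
    }))
  files <- c(landuse = file.path(dir, "landuse.geojson"),
             roads = file.path(dir, "roads.geojson"),
             met = file.path(dir, "met_stations.geojson"),
             population = file.path(dir, "population.asc"),
             altitude = file.path(dir, "altitude.asc"),
             config = file.path(dir, "city_config.json"))
  jsonlite::write_json(lu, files["landuse"], auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(rd, files["roads"], auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(ms, files["met"], auto_unbox = TRUE, digits = NA)
  write_ascii_grid(city$population, files["population"])
  write_ascii_grid(city$altitude, files["altitude"])
  jsonlite::write_json(city$config, files["config"], auto_unbox = TRUE,
                       digits = NA)
  invisible(files)
}
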