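#' Buffer predictor variables for LUR modelling
#'
#' Every predictor summarises a GIS layer inside a closed circular buffer
#' of radius 100, 200 or 500 m centred on a monitoring site, following the
#' usual LUR variable catalogue: land-use area fractions, road lengths by
#' class, distance to the nearest road of each class, population count and
#' density, traffic speed and volume, altitude, and meteorology. Column
#' names follow the <CODE><radius> convention (IND200, SEC100, DPRIM500);
#' unbuffered variables (ALT, TPROM, PPROM, HR, WD, WPROM) carry no radius.
#'
#' Units: land-use variables are fractions in [0, 1] (not percent); road
#' lengths and distances are metres; POB is persons and DEN persons/m^2;
#' VEL km/h and VOL veh/h. Per-column units are attached to the table.
#'
#' @name predictors
NULL

.BUFFER_RADII <- c(100, 200, 500)

.check_metric_crs <- function(crs) {
  if (is.null(crs)) return(invisible(TRUE))
  if (grepl("4326|degree|longlat|WGS", crs, ignore.case = TRUE)) {
    stop("layers must be in a projected metric CRS, not geographic degrees (",
         crs, ")")
  }
  invisible(TRUE)
}

.check_radius <- function(radius) {
  if (!radius %in% .BUFFER_RADII) {
    stop("radius must be one of ", paste(.BUFFER_RADII, collapse = ", "), " m")
  }
}

#' Land-use area fraction within a buffer
#'
#' Exact area of the category's polygons intersected with the closed disc,
#' divided by the disc area pi*r^2.
#'
#' @param city a \code{lur_city} (or any list with \code{landuse} and
#'   \code{crs}).
#' @param x,y site coordinates (m).
#' @param radius buffer radius in m (100, 200 or 500).
#' @param category land-use category code.
#' @return Fraction in [0, 1].
#' @export
landuse_fraction <- function(city, x, y, radius, category) {
  .check_metric_crs(city$crs)
  stopifnot(radius > 0)
  polys <- Filter(function(p) p$category == category, city$landuse)
  if (length(polys) == 0) return(0)
  # bounding-box prefilter: most parcels are far from the disc
  near <- Filter(function(p) {
    is.null(p$bbox) ||
      (p$bbox[1] <= x + radius && p$bbox[2] >= x - radius &&
       p$bbox[3] <= y + radius && p$bbox[4] >= y - radius)
  }, polys)
  if (length(near) == 0) return(0)
  a <- sum(vapply(near, function(p) disc_polygon_area(p$xy, x, y, radius), 0))
  min(a / (pi * radius^2), 1)
}

#' Total centreline length of a road class within a buffer
#'
#' @param roads road data frame with \code{class, x1, y1, x2, y2}.
#' @param x,y site coordinates.
#' @param radius buffer radius (m).
#' @param class road class (TRUNK, PRIM, SEC, TER, LOC).
#' @return Clipped length in metres.
#' @export
road_length_in_buffer <- function(roads, x, y, radius, class) {
  if (!class %in% .ROAD_CLASSES) {
    stop("unknown road class '", class, "'; expected one of ",
         paste(.ROAD_CLASSES, collapse = ", "))
  }
  r <- roads[roads$class == class, , drop = FALSE]
  if (nrow(r) == 0) return(0)
  sum(segment_length_in_disc(r$x1, r$y1, r$x2, r$y2, x, y, radius))
}

#' Distance from a site to the nearest road of a class
#'
#' When the class is absent from the layer the value is NA (a missing-value
#' sentinel, later removed by screening) with a warning: returning 0 would
#' fabricate proximity and infinity would distort regressions.
#'
#' @param roads road data frame.
#' @param x,y site coordinates.
#' @param class road class.
#' @return Minimum Euclidean distance (m), or NA if the class is absent.
#' @export
distance_to_road <- function(roads, x, y, class) {
  if (!class %in% .ROAD_CLASSES) {
    stop("unknown road class '", class, "'; expected one of ",
         paste(.ROAD_CLASSES, collapse = ", "))
  }
  r <- roads[roads$class == class, , drop = FALSE]
  if (nrow(r) == 0) {
    warning("no roads of class ", class, " in layer; distance is NA")
    return(NA_real_)
  }
  min(point_segment_distance(x, y, r$x1, r$y1, r$x2, r$y2))
}

#' Population count and density within a buffer
#'
#' Cell values (persons per cell) are weighted by the exact area of each
#' cell's intersection with the disc, removing the resolution bias a
#' centre-in-disc rule would introduce at 100 m radii.
#'
#' @param pop a \code{lur_raster} of persons per cell.
#' @param x,y site coordinates.
#' @param radius buffer radius (m).
#' @param allow_partial if FALSE (default), a disc extending beyond the
#'   raster is an error; if TRUE the covered part is used as observed.
#' @return Named vector c(POB = persons, DEN = persons/m^2), with
#'   DEN = POB / (pi r^2).
#' @export
population_in_buffer <- function(pop, x, y, radius, allow_partial = FALSE) {
  ext <- raster_extent(pop)
  if (!allow_partial &&
      (x - radius < ext[1] || x + radius > ext[3] ||
       y - radius < ext[2] || y + radius > ext[4])) {
    stop("buffer extends beyond the population raster; set allow_partial ",
         "= TRUE to use the covered part")
  }
  cs <- pop$cellsize
  jlo <- max(floor((x - radius - pop$xmin) / cs) + 1L, 1L)
  jhi <- min(ceiling((x + radius - pop$xmin) / cs), ncol(pop$values))
  ilo <- max(floor((y - radius - pop$ymin) / cs) + 1L, 1L)
  ihi <- min(ceiling((y + radius - pop$ymin) / cs), nrow(pop$values))
  if (jlo > jhi || ilo > ihi) return(c(POB = 0, DEN = 0))
  jj <- rep(jlo:jhi, each = ihi - ilo + 1L)
  ii <- rep(ilo:ihi, times = jhi - jlo + 1L)
  xlo <- pop$xmin + (jj - 1L) * cs
  ylo <- pop$ymin + (ii - 1L) * cs
  w <- disc_rect_area(x, y, radius, xlo, xlo + cs, ylo, ylo + cs) / cs^2
  pob <- sum(pop$values[cbind(ii, jj)] * w)
  c(POB = pob, DEN = pob / (pi * radius^2))
}

#' The predictor variable catalogue
#'
#' One row per column the full predictor table contains, with unit and
#' default expected coefficient sign. With traffic and meteorology layers
#' present the catalogue holds 69 variables (21 land-use fractions, 15 road
#' lengths, 15 distances, 6 population, 6 traffic, ALT, and 5 meteorology).
#'
#' @param radii buffer radii (m).
#' @param traffic,met include the traffic / meteorology blocks.
#' @return Data frame \code{name, group, unit, sign}.
#' @export
predictor_catalogue <- function(radii = .BUFFER_RADII, traffic = TRUE,
                                met = TRUE) {
  buf <- function(codes, group, unit, sign) {
    data.frame(name = as.vector(t(outer(codes, radii, paste0))),
               group = group, unit = unit, sign = sign,
               stringsAsFactors = FALSE)
  }
  rows <- list(
    buf(.LANDUSE_CATEGORIES, "landuse", "fraction",
        ifelse(.LANDUSE_CATEGORIES %in% c("RES", "DOT", "MIX"), "either", "+")),
    buf(.ROAD_CLASSES, "road_length", "m", "+"),
    buf(paste0("D", .ROAD_CLASSES), "road_distance", "m", "-"),
    buf(c("POB", "DEN"), "population", c("persons", "persons/m2"), "+"))
  if (traffic) rows <- c(rows, list(
    buf(c("VEL", "VOL"), "traffic", c("km/h", "veh/h"),
        c("either", "+"))))
  rows <- c(rows, list(
    data.frame(name = "ALT", group = "geography", unit = "m", sign = "-",
               stringsAsFactors = FALSE)))
  if (met) rows <- c(rows, list(
    data.frame(name = c("TPROM", "PPROM", "HR", "WD", "WPROM"),
               group = "meteorology",
               unit = c("degC", "mm", "%", "deg", "m/s"), sign = "either",
               stringsAsFactors = FALSE)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default expected-sign table
#'
#' Pattern-based mapping from predictor name to the theoretically expected
#' coefficient direction: emission proxies (industrial/central/commercial/
#' port land use, road length, population, traffic volume) positive;
#' distance to roads and altitude negative; residential/dotacional/mixed
#' land use, speed and meteorology unconstrained ("either"). Each catalogue
#' name matches exactly one pattern.
#'
#' @return Data frame \code{pattern, sign}.
#' @export
expected_signs <- function() {
  data.frame(
    pattern = c("^ALT$",
                "^D(TRUNK|TRON|PRIM|SEC|TER|LOC)",
                "^(TRUNK|PRIM|SEC|TER|LOC)",
                "^(IND|CEN|COM|PORT)",
                "^(RES|DOT|MIX)",
                "^(POB|DEN)",
                "^VOL", "^VEL",
                "^(TPROM|PPROM|HR|WD|WPROM)"),
    sign = c("-", "-", "+", "+", "either", "+", "+", "either", "either"),
    stringsAsFactors = FALSE)
}

#' Expected sign for a predictor name
#'
#' @param name predictor name(s).
#' @param signs a sign table from \code{\link{expected_signs}}.
#' @return Character vector of "+", "-" or "either".
#' @export
sign_for <- function(name, signs = expected_signs()) {
  vapply(name, function(nm) {
    hit <- which(vapply(signs$pattern, function(p) grepl(p, nm), TRUE))
    if (length(hit) == 0) return("either")
    signs$sign[hit[1]]
  }, "")
}

# length-weighted mean of a per-segment attribute over the buffer
.traffic_in_buffer <- function(roads, x, y, radius, attribute) {
  len <- segment_length_in_disc(roads$x1, roads$y1, roads$x2, roads$y2,
                                x, y, radius)
  tot <- sum(len)
  if (tot == 0) return(0)
  sum(len * roads[[attribute]]) / tot
}

#' Build the site-by-predictor table
#'
#' Computes every catalogue variable for each site. Omitted layers produce
#' omitted columns: without a traffic-attributed road layer there are no
#' VEL/VOL columns, and without meteorological surfaces no
#' TPROM/PPROM/HR/WD/WPROM columns (messaged, mirroring campaigns where a
#' city lacks enough met stations for a valid surface).
#'
#' @param city a \code{lur_city}.
#' @param sites data frame with unique \code{site_id} and \code{x, y}.
#' @param traffic optional road data frame carrying \code{speed} (km/h) and
#'   \code{volume} (veh/h) per segment, e.g. from
#'   \code{\link{assign_road_traffic}}.
#' @param met optional list with \code{TPROM} and \code{PPROM} rasters and
#'   a \code{stations} data frame (for HR/WD/WPROM nearest-station values),
#'   e.g. from \code{\link{build_met_surfaces}}.
#' @param radii buffer radii (m).
#' @param allow_partial passed to \code{\link{population_in_buffer}}; also
#'   renormalises land-use fractions by the in-extent disc area so they
#'   still sum to 1 near the boundary.
#' @param quiet suppress messages about omitted columns.
#' @return Data frame with \code{site_id} then one column per predictor;
#'   attributes \code{units} and \code{signs} give per-column metadata.
#' @export
build_predictor_table <- function(city, sites, traffic = NULL, met = NULL,
                                  radii = .BUFFER_RADII,
                                  allow_partial = FALSE, quiet = FALSE) {
  if (anyDuplicated(sites$site_id)) stop("duplicate site ids")
  .check_metric_crs(city$crs)
  n <- nrow(sites)
  out <- list(site_id = sites$site_id)

  ext <- city$extent
  extent_poly <- rbind(c(ext[1], ext[2]), c(ext[3], ext[2]),
                       c(ext[3], ext[4]), c(ext[1], ext[4]))

  for (r in radii) {
    # land use; near the boundary (allow_partial) renormalise by the
    # in-extent disc area so category fractions still partition
    denom <- vapply(seq_len(n), function(i) {
      if (allow_partial) {
        disc_polygon_area(extent_poly, sites$x[i], sites$y[i], r)
      } else pi * r^2
    }, 0)
    for (cat in .LANDUSE_CATEGORIES) {
      a <- vapply(seq_len(n), function(i) {
        landuse_fraction(city, sites$x[i], sites$y[i], r, cat) * pi * r^2
      }, 0)
      out[[paste0(cat, r)]] <- ifelse(denom > 0, pmin(a / denom, 1), 0)
    }
    for (cl in .ROAD_CLASSES) {
      out[[paste0(cl, r)]] <- vapply(seq_len(n), function(i) {
        road_length_in_buffer(city$roads, sites$x[i], sites$y[i], r, cl)
      }, 0)
    }
    pb <- t(vapply(seq_len(n), function(i) {
      population_in_buffer(city$population, sites$x[i], sites$y[i], r,
                           allow_partial = allow_partial)
    }, c(POB = 0, DEN = 0)))
    out[[paste0("POB", r)]] <- pb[, "POB"]
    out[[paste0("DEN", r)]] <- pb[, "DEN"]
    if (!is.null(traffic)) {
      out[[paste0("VEL", r)]] <- vapply(seq_len(n), function(i) {
        .traffic_in_buffer(traffic, sites$x[i], sites$y[i], r, "speed")
      }, 0)
      out[[paste0("VOL", r)]] <- vapply(seq_len(n), function(i) {
        .traffic_in_buffer(traffic, sites$x[i], sites$y[i], r, "volume")
      }, 0)
    }
  }

  # distances are unbuffered minima; radius-suffixed aliases are kept so
  # published equations (DPRIM500, DSEC200, ...) evaluate directly against
  # the table. Screening's |r| = 1 rule prunes the duplicates.
  for (cl in .ROAD_CLASSES) {
    d <- suppressWarnings(vapply(seq_len(n), function(i) {
      distance_to_road(city$roads, sites$x[i], sites$y[i], cl)
    }, 0))
    if (all(is.na(d)) && !quiet) {
      message("road class ", cl, " absent citywide; D", cl,
              " columns are NA sentinels")
    }
    for (r in radii) out[[paste0("D", cl, r)]] <- d
  }

  out[["ALT"]] <- raster_value_at(city$altitude, sites$x, sites$y)

  if (!is.null(met)) {
    out[["TPROM"]] <- raster_value_at(met$TPROM, sites$x, sites$y)
    out[["PPROM"]] <- raster_value_at(met$PPROM, sites$x, sites$y)
    st <- met$stations
    nearest <- vapply(seq_len(n), function(i) {
      which.min((st$x - sites$x[i])^2 + (st$y - sites$y[i])^2)
    }, 0L)
    out[["HR"]] <- st$HR[nearest]
    out[["WD"]] <- st$WD[nearest]
    out[["WPROM"]] <- st$WPROM[nearest]
  } else if (!quiet) {
    message("no meteorological surfaces supplied; ",
            "TPROM/PPROM/HR/WD/WPROM columns omitted")
  }

  tab <- as.data.frame(out, stringsAsFactors = FALSE)
  cat_tbl <- predictor_catalogue(radii, traffic = !is.null(traffic),
                                 met = !is.null(met))
  units <- stats::setNames(cat_tbl$unit, cat_tbl$name)
  attr(tab, "units") <- units[setdiff(names(tab), "site_id")]
  attr(tab, "signs") <- sign_for(setdiff(names(tab), "site_id"))
  tab
}

#' Write a predictor table as CSV plus a JSON metadata sidecar
#'
#' @param table predictor table from \code{\link{build_predictor_table}}.
#' @param path CSV output path; the sidecar is written to
#'   \code{<path>.meta.json}.
#' @export
write_predictor_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  meta <- list(units = as.list(attr(table, "units")),
               signs = as.list(attr(table, "signs")))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}
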