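#' Terrain-regression meteorological surfaces
#'
#' Station observations of mean temperature and precipitation are spread
#' over the city by regressing them on terrain covariates from the digital
#' terrain model -- altitude, slope, and land exposure (the azimuth of the
#' slope's inclination) -- and predicting every raster cell from its own
#' covariates. Cities with fewer than four stations are refused: too few
#' points for a valid spatial estimation. Exposure is circular, so it
#' enters the regression as a (sin, cos) pair rather than raw degrees.
#'
#' @name metsurface
NULL

#' Slope and exposure from a digital terrain model
#'
#' Central finite differences on cell centres (one-sided at the raster
#' edge). Slope is the gradient magnitude in degrees; exposure is the
#' azimuth of steepest descent in degrees clockwise from north, NA on
#' flat cells.
#'
#' @param dtm altitude \code{lur_raster} (m).
#' @param flat_tol gradient magnitude below which a cell is flagged flat.
#' @return List with \code{slope} and \code{aspect} rasters (degrees).
#' @export
derive_terrain <- function(dtm, flat_tol = 1e-8) {
  z <- dtm$values
  if (nrow(z) < 2 || ncol(z) < 2) {
    stop("cannot derive slope from a raster with a single row or column")
  }
  cs <- dtm$cellsize
  nr <- nrow(z); nc <- ncol(z)
  # d/dx across columns, d/dy across rows (row 1 = bottom)
  zx <- (z[, c(2:nc, nc)] - z[, c(1, 1:(nc - 1))]) /
    (cs * (rep(1, nr) %o% c(1, rep(2, nc - 2), 1)))
  zy <- (z[c(2:nr, nr), ] - z[c(1, 1:(nr - 1)), ]) /
    (cs * (c(1, rep(2, nr - 2), 1) %o% rep(1, nc)))
  grad <- sqrt(zx^2 + zy^2)
  slope <- atan(grad) * 180 / pi
  aspect <- (atan2(-zx, -zy) * 180 / pi) %% 360
  aspect[grad < flat_tol] <- NA_real_
  list(slope = lur_raster(slope, dtm$xmin, dtm$ymin, cs),
       aspect = lur_raster(aspect, dtm$xmin, dtm$ymin, cs))
}

# covariate record at arbitrary points: altitude, slope, exposure sin/cos
.terrain_covariates <- function(dtm, terrain, x, y) {
  asp <- raster_value_at(terrain$aspect, x, y)
  asp_rad <- asp * pi / 180
  data.frame(alt = raster_value_at(dtm, x, y),
             slope = raster_value_at(terrain$slope, x, y),
             exp_sin = ifelse(is.na(asp), 0, sin(asp_rad)),
             exp_cos = ifelse(is.na(asp), 0, cos(asp_rad)))
}

#' Fit a meteorological surface by terrain regression
#'
#' OLS of the station values on the chosen terrain covariates, then
#' cellwise prediction over the DTM. Optionally adds an inverse-distance
#' interpolation of the station residuals (regression-only is the
#' default).
#'
#' @param stations data frame with \code{x, y} and the observed variable.
#' @param dtm altitude \code{lur_raster}.
#' @param variable name of the observed column (e.g. "TPROM", "PPROM").
#' @param covariates subset of c("alt", "slope", "exposure").
#' @param residual_idw add inverse-distance-weighted residual correction.
#' @return List with \code{model} (a \code{met_model}: variable,
#'   coefficients, residual SD, n_stations) and \code{raster} (predicted
#'   surface).
#' @export
fit_met_surface <- function(stations, dtm, variable = "TPROM",
                            covariates = c("alt", "slope", "exposure"),
                            residual_idw = FALSE) {
  n <- nrow(stations)
  if (n < 4) {
    stop("fewer than four meteorological stations do not allow a valid ",
         "spatial estimation (got ", n, ")")
  }
  stopifnot(variable %in% names(stations),
            all(covariates %in% c("alt", "slope", "exposure")))
  terrain <- derive_terrain(dtm)
  cov_names <- c(alt = "alt", slope = "slope")[
    covariates[covariates != "exposure"]]
  if ("exposure" %in% covariates) cov_names <- c(cov_names, "exp_sin", "exp_cos")
  cov_names <- unname(cov_names)
  if (n < length(cov_names) + 2) {
    stop("too few stations (", n, ") for covariate set {",
         paste(covariates, collapse = ", "), "}")
  }
  st_cov <- .terrain_covariates(dtm, terrain, stations$x, stations$y)
  if (any(!is.finite(as.matrix(st_cov[cov_names])))) {
    stop("non-finite terrain covariates at station locations")
  }
  dat <- cbind(y = stations[[variable]], st_cov[cov_names])
  fit <- stats::lm(stats::reformulate(cov_names, "y"), data = dat)

  cc <- raster_centres(dtm)
  gx <- rep(cc$x, each = length(cc$y)); gy <- rep(cc$y, times = length(cc$x))
  grid_cov <- .terrain_covariates(dtm, terrain, gx, gy)
  pred <- stats::predict(fit, newdata = grid_cov)
  if (residual_idw) {
    res <- stats::residuals(fit)
    d2 <- outer(gx, stations$x, "-")^2 + outer(gy, stations$y, "-")^2
    w <- 1 / pmax(d2, 1)
    pred <- pred + as.vector((w %*% res) / rowSums(w))
  }
  raster <- lur_raster(matrix(pred, nrow = length(cc$y), ncol = length(cc$x)),
                       dtm$xmin, dtm$ymin, dtm$cellsize)
  model <- structure(list(variable = variable,
                          coefficients = stats::coef(fit),
                          residual_sd = stats::sigma(fit),
                          n_stations = n,
                          residual_idw = residual_idw),
                     class = "met_model")
  list(model = model, raster = raster)
}

#' @export
print.met_model <- function(x, ...) {
  cat(sprintf("<met_model> %s on %d stations, residual SD %.3g\n",
              x$variable, x$n_stations, x$residual_sd))
  print(round(x$coefficients, 6))
  invisible(x)
}

#' Build the city's meteorological surfaces
#'
#' Fits TPROM and PPROM terrain-regression surfaces from the city's
#' station network; HR, WD and WPROM are passed through as
#' nearest-station values by the predictor extraction (no surface is
#' modelled for them).
#'
#' @param city a \code{lur_city}.
#' @param covariates terrain covariates for the regression.
#' @return List with \code{TPROM} and \code{PPROM} rasters,
#'   \code{stations}, and the fitted \code{models}; or NULL (with a
#'   message) when the city has fewer than four stations.
#' @export
build_met_surfaces <- function(city, covariates = c("alt", "slope",
                                                    "exposure")) {
  st <- city$met_stations
  if (nrow(st) < 4) {
    message("city has fewer than four meteorological stations; no valid ",
            "spatial estimation, meteorological predictors will be omitted")
    return(NULL)
  }
  t_fit <- fit_met_surface(st, city$altitude, "TPROM", covariates)
  p_fit <- fit_met_surface(st, city$altitude, "PPROM", covariates)
  list(TPROM = t_fit$raster, PPROM = p_fit$raster, stations = st,
       models = list(TPROM = t_fit$model, PPROM = p_fit$model))
}
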