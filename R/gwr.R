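#' Geographically weighted regression and concentration surfaces
#'
#' The selected LUR equation is locally recalibrated by geographically
#' weighted regression (GWR): at each calibration point a weighted least
#' squares fit with distance-kernel weights on inter-site distances yields
#' spatially varying coefficients. The fitted model is then evaluated on a
#' regular point mesh (200 m spacing by default) over the city extent and
#' interpolated to a continuous raster with an interpolating thin-plate
#' spline.
#'
#' @name gwr_surface
NULL

.gwr_kernel <- function(d, bandwidth, kernel) {
  switch(kernel,
         gaussian = exp(-0.5 * (d / bandwidth)^2),
         bisquare = ifelse(d < bandwidth, (1 - (d / bandwidth)^2)^2, 0),
         stop("unknown kernel '", kernel, "'"))
}

# weighted least squares at one focal point; NULL if the weighted design
# is effectively singular
.local_fit <- function(y, Xm, w) {
  keep <- w > 1e-10
  if (sum(keep) < ncol(Xm)) return(NULL)
  sw <- sqrt(w[keep])
  A <- Xm[keep, , drop = FALSE] * sw
  b <- y[keep] * sw
  qr_A <- qr(A)
  if (qr_A$rank < ncol(Xm)) return(NULL)
  qr.coef(qr_A, b)
}

#' Fit a geographically weighted regression
#'
#' @param sites data frame with \code{x, y} (calibration locations).
#' @param y outcome at the sites (on the modelled scale).
#' @param X data frame of the selected model's predictors at the sites.
#' @param kernel "gaussian" (default) or "bisquare".
#' @param bandwidth kernel bandwidth in metres (> 0).
#' @return A \code{gwr_result}: per-site local coefficient matrix,
#'   kernel, bandwidth, local predictions and a global fit for reference.
#' @export
fit_gwr <- function(sites, y, X, kernel = c("gaussian", "bisquare"),
                    bandwidth) {
  kernel <- match.arg(kernel)
  stopifnot(bandwidth > 0)
  X <- as.data.frame(X)
  n <- length(y)
  Xm <- cbind(`(Intercept)` = 1, as.matrix(X))
  coefs <- matrix(NA_real_, n, ncol(Xm),
                  dimnames = list(NULL, colnames(Xm)))
  for (i in seq_len(n)) {
    d <- sqrt((sites$x - sites$x[i])^2 + (sites$y - sites$y[i])^2)
    w <- .gwr_kernel(d, bandwidth, kernel)
    cf <- .local_fit(y, Xm, w)
    if (is.null(cf)) {
      stop(sprintf(paste0("bandwidth %g m leaves fewer effective ",
                          "observations than parameters at site %d (%.0f, %.0f)"),
                   bandwidth, i, sites$x[i], sites$y[i]))
    }
    coefs[i, ] <- cf
  }
  fitted <- rowSums(Xm * coefs)
  global <- fit_ols(y, X)
  structure(list(sites = sites[, c("x", "y")], coefficients = coefs,
                 kernel = kernel, bandwidth = bandwidth,
                 fitted = fitted, y = y, X = X,
                 global = global$coefficients,
                 r2 = 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)),
            class = "gwr_result")
}

#' @export
print.gwr_result <- function(x, ...) {
  cat(sprintf("<gwr_result> %d sites, %s kernel, bandwidth %g m, local R2 %.3f\n",
              nrow(x$coefficients), x$kernel, x$bandwidth, x$r2))
  cat("  coefficient ranges:\n")
  rng <- apply(x$coefficients, 2, range)
  for (j in colnames(rng)) {
    cat(sprintf("    %s: [%.4g, %.4g]\n", j, rng[1, j], rng[2, j]))
  }
  invisible(x)
}

#' Select a GWR bandwidth by leave-one-out cross-validation
#'
#' For each candidate bandwidth, each site is predicted from a local fit
#' that excludes it; the bandwidth minimising the mean squared LOO error
#' is returned. Candidates within 0.5% of the minimum are treated as
#' ties and resolved toward the larger (smoother) bandwidth, so
#' homogeneous data select the flattest kernel offered.
#'
#' @param sites,y,X as in \code{\link{fit_gwr}}.
#' @param kernel kernel name.
#' @param candidates numeric vector of at least 3 candidate bandwidths (m).
#' @return The selected bandwidth.
#' @export
select_bandwidth <- function(sites, y, X, kernel = c("gaussian", "bisquare"),
                             candidates) {
  kernel <- match.arg(kernel)
  if (length(candidates) < 3) stop("need at least 3 candidate bandwidths")
  X <- as.data.frame(X)
  Xm <- cbind(1, as.matrix(X))
  n <- length(y)
  cv <- vapply(sort(candidates), function(bw) {
    err <- vapply(seq_len(n), function(i) {
      d <- sqrt((sites$x[-i] - sites$x[i])^2 + (sites$y[-i] - sites$y[i])^2)
      w <- .gwr_kernel(d, bw, kernel)
      cf <- .local_fit(y[-i], Xm[-i, , drop = FALSE], w)
      if (is.null(cf)) return(NA_real_)
      (y[i] - sum(Xm[i, ] * cf))^2
    }, 0)
    if (anyNA(err)) Inf else mean(err)
  }, 0)
  if (all(!is.finite(cv))) stop("no candidate bandwidth is feasible")
  cands <- sort(candidates)
  # candidates within 0.5% of the minimum LOO error are ties (beyond a
  # few kernel widths the error curve is flat to noise) and resolve
  # toward the larger, smoother bandwidth
  max(cands[cv <= min(cv) * 1.005])
}

#' Regular point mesh over an extent
#'
#' Axis-aligned lattice anchored at the extent's lower-left corner,
#' including boundary rows/columns that fall on the lattice.
#'
#' @param extent c(xmin, ymin, xmax, ymax).
#' @param spacing mesh spacing in metres (200 m default).
#' @return Data frame \code{x, y} of mesh points.
#' @export
make_mesh <- function(extent, spacing = 200) {
  stopifnot(spacing > 0, extent[3] > extent[1], extent[4] > extent[2])
  if (spacing > extent[3] - extent[1] || spacing > extent[4] - extent[2]) {
    warning("spacing exceeds an extent dimension; mesh degenerates")
  }
  xs <- seq(extent[1], extent[3], by = spacing)
  ys <- seq(extent[2], extent[4], by = spacing)
  data.frame(x = rep(xs, times = length(ys)),
             y = rep(ys, each = length(xs)))
}

#' Fit an interpolating thin-plate spline
#'
#' Radial basis U(r) = r^2 log(r) plus an affine trend, coefficients from
#' the standard TPS linear system with no smoothing penalty, so the
#' surface reproduces the data exactly at the knots.
#'
#' @param x,y,value knot coordinates and values.
#' @return A \code{tps_fit} for \code{\link{predict_tps}}.
#' @export
fit_tps <- function(x, y, value) {
  n <- length(x)
  stopifnot(n >= 3, length(y) == n, length(value) == n)
  # work in scaled coordinates for conditioning; the interpolant is
  # invariant to an affine rescaling of the plane (up to the same basis)
  ctr <- c(mean(x), mean(y))
  scl <- max(max(x) - min(x), max(y) - min(y), 1)
  xs <- (x - ctr[1]) / scl; ys <- (y - ctr[2]) / scl
  U <- function(r) ifelse(r > 0, r * r * log(r), 0)
  d <- sqrt(outer(xs, xs, "-")^2 + outer(ys, ys, "-")^2)
  K <- U(d)
  P <- cbind(1, xs, ys)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- c(value, 0, 0, 0)
  sol <- qr.solve(qr(A, LAPACK = TRUE), rhs)
  structure(list(x = x, y = y, ctr = ctr, scl = scl,
                 w = sol[1:n], a = sol[(n + 1):(n + 3)]),
            class = "tps_fit")
}

#' Evaluate a thin-plate spline
#'
#' @param fit a \code{tps_fit}.
#' @param x,y evaluation coordinates.
#' @return Interpolated values.
#' @export
predict_tps <- function(fit, x, y) {
  U <- function(r) ifelse(r > 0, r * r * log(r), 0)
  xs <- (x - fit$ctr[1]) / fit$scl; ys <- (y - fit$ctr[2]) / fit$scl
  fx <- (fit$x - fit$ctr[1]) / fit$scl; fy <- (fit$y - fit$ctr[2]) / fit$scl
  d <- sqrt(outer(xs, fx, "-")^2 + outer(ys, fy, "-")^2)
  as.vector(U(d) %*% fit$w) + fit$a[1] + fit$a[2] * xs + fit$a[3] * ys
}

#' Predict a concentration surface on a mesh and interpolate to a raster
#'
#' Builds the predictor table at the mesh points (buffers near the city
#' boundary use the clipped disc with fraction renormalisation), evaluates
#' the model at each point -- globally for a \code{lur_model}, or by
#' kernel-weighted local calibration at each mesh point for a
#' \code{gwr_result} (never nearest-site coefficient copying) -- and fits
#' an interpolating thin-plate spline through the mesh values to produce
#' the raster.
#'
#' @param model a \code{lur_model} or \code{gwr_result}.
#' @param city a \code{lur_city}.
#' @param mesh mesh data frame from \code{\link{make_mesh}} (built over
#'   the city extent if NULL).
#' @param spacing mesh spacing when \code{mesh} is NULL.
#' @param resolution output raster cell size (m).
#' @param traffic,met optional layers passed to
#'   \code{\link{build_predictor_table}}.
#' @return A \code{surface_grid}: mesh with predicted values, the
#'   interpolated raster, and metadata recording which coefficients
#'   (global or GWR-local) produced it.
#' @export
predict_surface <- function(model, city, mesh = NULL, spacing = 200,
                            resolution = 50, traffic = NULL, met = NULL) {
  if (is.null(mesh)) mesh <- make_mesh(city$extent, spacing)
  is_gwr <- inherits(model, "gwr_result")
  need <- if (is_gwr) names(model$X) else model$terms$predictor
  mesh_sites <- data.frame(site_id = sprintf("M%05d", seq_len(nrow(mesh))),
                           x = mesh$x, y = mesh$y)
  tab <- build_predictor_table(city, mesh_sites, traffic = traffic,
                               met = met, allow_partial = TRUE, quiet = TRUE)
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    stop("predictors required by the model are not computable here: ",
         paste(missing, collapse = ", "))
  }
  if (is_gwr) {
    Xm <- cbind(1, as.matrix(tab[need]))
    Xc <- cbind(1, as.matrix(model$X))
    vals <- vapply(seq_len(nrow(mesh)), function(i) {
      d <- sqrt((model$sites$x - mesh$x[i])^2 + (model$sites$y - mesh$y[i])^2)
      w <- .gwr_kernel(d, model$bandwidth, model$kernel)
      cf <- .local_fit(model$y, Xc, w)
      if (is.null(cf)) return(NA_real_)
      sum(Xm[i, ] * cf)
    }, 0)
    coef_source <- "gwr-local"
  } else {
    vals <- predict(model, tab)
    if (length(vals) == 1) vals <- rep(vals, nrow(mesh))
    coef_source <- "global"
  }
  tps <- fit_tps(mesh$x, mesh$y, vals)
  ext <- city$extent
  ncx <- ceiling((ext[3] - ext[1]) / resolution)
  ncy <- ceiling((ext[4] - ext[2]) / resolution)
  cx <- ext[1] + (seq_len(ncx) - 0.5) * resolution
  cy <- ext[2] + (seq_len(ncy) - 0.5) * resolution
  gx <- rep(cx, each = ncy); gy <- rep(cy, times = ncx)
  raster <- lur_raster(matrix(predict_tps(tps, gx, gy), nrow = ncy, ncol = ncx),
                       ext[1], ext[2], resolution)
  structure(list(mesh = cbind(mesh, value = vals), spacing = spacing,
                 raster = raster, tps = tps,
                 coef_source = coef_source),
            class = "surface_grid")
}

#' @export
print.surface_grid <- function(x, ...) {
  cat(sprintf("<surface_grid> %d mesh points (%g m spacing, %s coefficients), raster %d x %d\n",
              nrow(x$mesh), x$spacing, x$coef_source,
              nrow(x$raster$values), ncol(x$raster$values)))
  cat(sprintf("  predicted range: [%.3g, %.3g]\n",
              min(x$mesh$value, na.rm = TRUE), max(x$mesh$value, na.rm = TRUE)))
  invisible(x)
}
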