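#' Speed-density-flow fundamental diagrams
#'
#' Traffic volume is not observed directly at LUR monitoring sites; it is
#' estimated from observed link speeds through a fitted speed-density
#' relation v(k) and the identity q = k * v * lanes. Six classical
#' functional forms are supported; since the literature states them with
#' varying conventions, the canonical equations used throughout this
#' package are pinned here:
#'
#' \describe{
#'   \item{greenshields}{v = vf (1 - k/kj)}
#'   \item{greenberg}{v = v0 ln(kj / k)}
#'   \item{underwood}{v = vf exp(-k / k0)}
#'   \item{pipes}{v = vf (1 - k/kj)^2}
#'   \item{drew}{v = vf (1 - sqrt(k/kj))}
#'   \item{may_keller}{v = vf (1 - (k/kj)^a), exponent a free}
#' }
#'
#' with speed v in km/h, density k in veh/km/lane, free-flow speed vf,
#' jam density kj, Greenberg optimal speed v0 and Underwood optimal
#' density k0. All six v(k) curves are strictly decreasing on their
#' domain, so speed-to-density inversion is single-valued; the stored
#' traffic regime (interrupted / semi-interrupted / uninterrupted) records
#' which operating branch of the flow-speed relation the observations
#' represent.
#'
#' @name traffic
NULL

.FLOW_FORMS <- c("greenshields", "greenberg", "underwood", "pipes", "drew",
                 "may_keller")
.FLOW_REGIMES <- c("interrupted", "semi-interrupted", "uninterrupted")

#' Speed predicted by a fundamental-diagram form
#'
#' @param model a \code{flow_model} (or list with \code{form} and
#'   \code{parameters}).
#' @param k density (veh/km/lane), vectorised.
#' @return Speed in km/h, floored at 0 beyond the form's domain.
#' @export
flow_speed <- function(model, k) {
  p <- as.list(model$parameters)
  v <- switch(model$form,
    greenshields = p[["vf"]] * (1 - k / p[["kj"]]),
    greenberg    = p[["v0"]] * log(p[["kj"]] / k),
    underwood    = p[["vf"]] * exp(-k / p[["k0"]]),
    pipes        = p[["vf"]] * pmax(1 - k / p[["kj"]], 0)^2,
    drew         = p[["vf"]] * (1 - sqrt(pmax(k, 0) / p[["kj"]])),
    may_keller   = p[["vf"]] * (1 - (pmax(k, 0) / p[["kj"]])^p[["a"]]),
    stop("unknown form '", model$form, "'"))
  pmax(v, 0)
}

# least-squares estimation on the linearising transform of each form;
# returns named parameter vector or NULL when invalid/non-convergent
.fit_form_once <- function(form, k, v) {
  est <- tryCatch(switch(form,
    greenshields = {
      cf <- stats::coef(stats::lm(v ~ k))
      if (cf[2] >= 0 || cf[1] <= 0) NULL else
        c(vf = unname(cf[1]), kj = unname(-cf[1] / cf[2]))
    },
    greenberg = {
      cf <- stats::coef(stats::lm(v ~ log(k)))
      v0 <- unname(-cf[2])
      if (v0 <= 0) NULL else c(v0 = v0, kj = unname(exp(cf[1] / v0)))
    },
    underwood = {
      if (any(v <= 0)) return(NULL)
      cf <- stats::coef(stats::lm(log(v) ~ k))
      if (cf[2] >= 0) NULL else
        c(vf = unname(exp(cf[1])), k0 = unname(-1 / cf[2]))
    },
    pipes = {
      if (any(v < 0)) return(NULL)
      cf <- stats::coef(stats::lm(sqrt(v) ~ k))
      if (cf[2] >= 0 || cf[1] <= 0) NULL else
        c(vf = unname(cf[1]^2), kj = unname(-cf[1] / cf[2]))
    },
    drew = {
      cf <- stats::coef(stats::lm(v ~ sqrt(k)))
      if (cf[2] >= 0 || cf[1] <= 0) NULL else
        c(vf = unname(cf[1]), kj = unname((cf[1] / cf[2])^2))
    },
    may_keller = {
      # profile the exponent over a grid; conditional on a the model is
      # linear in k^a
      best <- NULL; best_sse <- Inf
      for (a in seq(0.5, 4, by = 0.25)) {
        ka <- k^a
        cf <- stats::coef(stats::lm(v ~ ka))
        if (cf[2] >= 0 || cf[1] <= 0) next
        sse <- sum((v - (cf[1] + cf[2] * ka))^2)
        if (sse < best_sse) {
          best_sse <- sse
          best <- c(vf = unname(cf[1]),
                    kj = unname((cf[1] / -cf[2])^(1 / a)), a = a)
        }
      }
      best
    }), error = function(e) NULL)
  if (!is.null(est) && any(!is.finite(est) | est <= 0)) return(NULL)
  est
}

#' Fit speed-density-flow models and select the best form by RMSE
#'
#' For each candidate form, parameters are estimated by least squares on
#' bootstrap resamples (sampling observation pairs with replacement) and
#' averaged. Each resample's fit is scored by its RMSE on the
#' out-of-bag observations -- always on the speed scale -- and the form
#' with the smallest mean out-of-bag RMSE is selected; with noise-free
#' data every resample fits exactly and the scores collapse to the
#' in-sample RMSE. Scoring out-of-bag keeps forms that nest one another
#' (may_keller contains greenshields at exponent 1) from winning on
#' overfit alone. Forms whose estimates are invalid on more than half
#' the resamples are excluded with a warning. Score ties within 1e-9 are
#' resolved by catalogue order (greenshields first).
#'
#' @param observations data frame with \code{density} (veh/km/lane, > 0)
#'   and \code{speed} (km/h) columns; at least 10 rows.
#' @param forms subset of forms to try (default all six).
#' @param n_resamples bootstrap resamples per form.
#' @param seed integer seed.
#' @param regime traffic regime label stored on the model.
#' @return A \code{flow_model}: form, parameters, regime, rmse (km/h),
#'   with the per-form RMSE table attached as \code{candidates}.
#' @export
fit_flow_model <- function(observations, forms = .FLOW_FORMS,
                           n_resamples = 200, seed = 1,
                           regime = "uninterrupted") {
  stopifnot(all(forms %in% .FLOW_FORMS), regime %in% .FLOW_REGIMES)
  k <- observations$density; v <- observations$speed
  if (length(k) < 10) stop("need at least 10 (density, speed) observations")
  if (any(k <= 0)) stop("densities must be positive")
  if (stats::sd(k) == 0 || stats::sd(v) == 0) {
    stop("degenerate observations: density and speed must both vary")
  }
  n <- length(k)
  # one shared set of resample indices so form scores are paired
  idx_list <- withr::with_seed(seed, {
    lapply(seq_len(n_resamples), function(b) sample.int(n, n, replace = TRUE))
  })
  fits <- lapply(forms, function(form) {
    pars_list <- list(); oob <- numeric(0)
    for (idx in idx_list) {
      est <- .fit_form_once(form, k[idx], v[idx])
      if (is.null(est)) next
      pars_list[[length(pars_list) + 1L]] <- est
      out <- setdiff(seq_len(n), idx)
      hold <- if (length(out) > 0) out else seq_len(n)
      vhat <- flow_speed(list(form = form, parameters = est), k[hold])
      oob <- c(oob, sqrt(mean((v[hold] - vhat)^2)))
    }
    if (length(pars_list) < n_resamples / 2) return(NULL)
    pars <- colMeans(do.call(rbind, pars_list))
    vhat <- flow_speed(list(form = form, parameters = pars), k)
    list(form = form, parameters = pars, score = mean(oob),
         rmse = sqrt(mean((v - vhat)^2)))
  })
  names(fits) <- forms
  dropped <- forms[vapply(fits, is.null, TRUE)]
  if (length(dropped) > 0) {
    warning("forms excluded (non-convergent): ",
            paste(dropped, collapse = ", "))
  }
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) stop("no functional form could be fitted")
  scores <- vapply(fits, `[[`, 0, "score")
  best <- fits[[which(scores <= min(scores) + 1e-9)[1]]]
  structure(list(form = best$form, parameters = best$parameters,
                 regime = regime, rmse = best$rmse, n_obs = n,
                 candidates = data.frame(form = names(scores),
                                         oob_rmse = unname(scores),
                                         rmse = vapply(fits, `[[`, 0, "rmse"),
                                         row.names = NULL)),
            class = "flow_model")
}

#' @export
print.flow_model <- function(x, ...) {
  cat(sprintf("<flow_model> %s (%s regime), RMSE %.4g km/h\n",
              x$form, x$regime, x$rmse))
  cat("  ", paste(sprintf("%s = %.4g", names(x$parameters), x$parameters),
                  collapse = ", "), "\n")
  invisible(x)
}

#' Estimate traffic volume from speed via the fitted fundamental diagram
#'
#' Inverts the (strictly decreasing) speed-density relation to the density
#' at the observed speed and returns q = k * v * lanes in veh/h.
#'
#' @param model a \code{flow_model}.
#' @param speed observed speed (km/h), vectorised; must be positive and,
#'   for forms with a free-flow speed, at most vf.
#' @param lanes lane count; flow is linear in lanes.
#' @return Flow in vehicles per hour.
#' @export
estimate_volume <- function(model, speed, lanes = 1) {
  p <- as.list(model$parameters)
  if (any(speed <= 0)) stop("speed must be positive")
  if (!is.null(p[["vf"]]) && any(speed > p[["vf"]] + 1e-12)) {
    stop(sprintf("speed exceeds the free-flow bound vf = %.4g km/h", p[["vf"]]))
  }
  k <- switch(model$form,
    greenshields = p[["kj"]] * (1 - speed / p[["vf"]]),
    greenberg    = p[["kj"]] * exp(-speed / p[["v0"]]),
    underwood    = p[["k0"]] * log(p[["vf"]] / speed),
    pipes        = p[["kj"]] * (1 - sqrt(speed / p[["vf"]])),
    drew         = p[["kj"]] * (1 - speed / p[["vf"]])^2,
    may_keller   = p[["kj"]] * (1 - speed / p[["vf"]])^(1 / p[["a"]]))
  k * speed * lanes
}

#' Simulate (density, speed) sensor observations from a known form
#'
#' @param form one of the six forms.
#' @param parameters named parameter vector for the form.
#' @param n number of observations.
#' @param noise_sd speed noise SD (km/h).
#' @param seed integer seed.
#' @return Data frame \code{density, speed}.
#' @export
simulate_flow_observations <- function(form, parameters, n = 200,
                                       noise_sd = 2, seed = 1) {
  parameters <- as.list(parameters)
  withr::with_seed(seed, {
    kmax <- if (!is.null(parameters[["kj"]])) 0.9 * parameters[["kj"]] else
      3 * parameters[["k0"]]
    k <- stats::runif(n, 0.02 * kmax, kmax)
    v <- flow_speed(list(form = form, parameters = parameters), k)
    data.frame(density = k,
               speed = pmax(v + stats::rnorm(n, 0, noise_sd), 0.1))
  })
}

# class defaults used when attributing a synthetic road network
.CLASS_SPEED <- c(TRUNK = 60, PRIM = 45, SEC = 35, TER = 25, LOC = 15)
.CLASS_REGIME <- c(TRUNK = "uninterrupted", PRIM = "semi-interrupted",
                   SEC = "interrupted", TER = "interrupted",
                   LOC = "interrupted")

#' Attribute a road network with speeds and estimated volumes
#'
#' Draws a plausible mean speed per segment around its class's typical
#' value and converts it to a volume through a per-class fundamental
#' diagram (default: Greenshields with vf 40% above the class speed and
#' jam density 120 veh/km/lane), times the lane count.
#'
#' @param city a \code{lur_city}.
#' @param models optional named list of \code{flow_model}s per road class;
#'   defaults are built per class as described.
#' @param speed_sd SD of the per-segment speed draw (km/h).
#' @param seed integer seed.
#' @return The city's road data frame with \code{speed}, \code{volume} and
#'   \code{regime} columns added.
#' @export
assign_road_traffic <- function(city, models = NULL, speed_sd = 3, seed = 1) {
  roads <- city$roads
  if (nrow(roads) == 0) return(cbind(roads, speed = numeric(0),
                                     volume = numeric(0),
                                     regime = character(0)))
  withr::with_seed(seed, {
    base <- .CLASS_SPEED[roads$class]
    speed <- pmax(base + stats::rnorm(nrow(roads), 0, speed_sd), 5)
    volume <- numeric(nrow(roads))
    for (cl in unique(roads$class)) {
      m <- if (!is.null(models) && !is.null(models[[cl]])) models[[cl]] else
        structure(list(form = "greenshields",
                       parameters = c(vf = unname(.CLASS_SPEED[cl]) * 1.4,
                                      kj = 120),
                       regime = unname(.CLASS_REGIME[cl])),
                  class = "flow_model")
      idx <- roads$class == cl
      sp <- pmin(speed[idx], m$parameters[["vf"]] * 0.98)
      speed[idx] <- sp
      volume[idx] <- estimate_volume(m, sp, lanes = roads$lanes[idx])
    }
    roads$speed <- speed
    roads$volume <- volume
    roads$regime <- unname(.CLASS_REGIME[roads$class])
    roads
  })
}
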