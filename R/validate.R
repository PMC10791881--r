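#' Annual means, LOOCV and agreement statistics
#'
#' Annual site concentrations are the mean of the two campaign means
#' (each campaign mean averaging its valid weekly values); sites that
#' contribute only one successful campaign are excluded from the annual
#' analysis. Model stability is assessed by leave-one-out
#' cross-validation with the selected term set held fixed, and instrument
#' agreement by Bland-Altman limits.
#'
#' @name validate
NULL

#' Aggregate weekly measurements to annual site means
#'
#' @param measurements measurement table (\code{site_id, campaign, week,
#'   value}; campaigns labelled dry/rainy). NA values are invalid weeks.
#' @return List with \code{means} (data frame \code{site_id, x, y,
#'   dry, rainy, annual}) and \code{excluded} (data frame
#'   \code{site_id, reason}: "single campaign" or "no valid campaign").
#' @export
annual_means <- function(measurements) {
  stopifnot(all(c("site_id", "campaign", "week", "value") %in%
                  names(measurements)))
  stopifnot(all(measurements$campaign %in% c("dry", "rainy")))
  ids <- unique(measurements$site_id)
  camp_mean <- function(id, camp) {
    v <- measurements$value[measurements$site_id == id &
                              measurements$campaign == camp]
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else mean(v)
  }
  dry <- vapply(ids, camp_mean, 0, camp = "dry")
  rainy <- vapply(ids, camp_mean, 0, camp = "rainy")
  n_valid <- (!is.na(dry)) + (!is.na(rainy))
  excluded <- data.frame(
    site_id = ids[n_valid < 2],
    reason = ifelse(n_valid[n_valid < 2] == 1, "single campaign",
                    "no valid campaign"),
    stringsAsFactors = FALSE)
  keep <- n_valid == 2
  xy <- measurements[match(ids, measurements$site_id), c("x", "y")]
  means <- data.frame(site_id = ids[keep],
                      x = if (!is.null(xy$x)) xy$x[keep] else NA_real_,
                      y = if (!is.null(xy$y)) xy$y[keep] else NA_real_,
                      dry = dry[keep], rainy = rainy[keep],
                      annual = (dry[keep] + rainy[keep]) / 2,
                      stringsAsFactors = FALSE)
  rownames(means) <- NULL
  list(means = means, excluded = excluded)
}

#' Leave-one-out cross-validation of a LUR model
#'
#' The selected variable set is held fixed; for each site the
#' coefficients are refitted without it and the site predicted. CV R2 is
#' the squared Pearson correlation between observed and left-out
#' predictions on the concentration scale (a 1 - SSE/SST variant is also
#' reported); log-transform models are back-transformed with exp() before
#' computing CV statistics. The cross-validated squared error is reported
#' both as a mean and as a sum.
#'
#' @param table predictor table at the sites.
#' @param y observed concentrations.
#' @param terms character vector of predictor names (the fixed term set).
#' @param transform "identity" or "log".
#' @param reselect if TRUE, the full supervised selection is re-run in
#'   each fold (honesty analysis) instead of keeping terms fixed.
#' @param ... passed to \code{\link{supervised_select}} when reselecting.
#' @return A \code{validation_report}: model R2, CV R2 (both
#'   conventions), R2 gap in percentage points, mean/sum squared error,
#'   and the per-site (observed, predicted) pairs.
#' @export
loocv <- function(table, y, terms, transform = c("identity", "log"),
                  reselect = FALSE, ...) {
  transform <- match.arg(transform)
  X <- .numeric_predictors(table)
  n <- length(y)
  if (!reselect) {
    missing <- setdiff(terms, names(X))
    if (length(missing) > 0) stop("terms not in table: ",
                                  paste(missing, collapse = ", "))
    if (n <= length(terms) + 2) stop("n must exceed p + 2 for LOOCV")
  }
  if (stats::sd(y) == 0) stop("observed concentrations are constant; CV R2 undefined")
  yt <- if (transform == "log") log(y) else y
  pred <- vapply(seq_len(n), function(i) {
    if (reselect) {
      m <- suppressWarnings(
        supervised_select(X[-i, , drop = FALSE], y[-i],
                          transform = transform, ...))
      as.numeric(predict(m, X[i, , drop = FALSE]))
    } else {
      f <- tryCatch(fit_ols(yt[-i], X[-i, terms, drop = FALSE]),
                    error = function(e) {
                      stop("fold ", i, " failed: ", conditionMessage(e))
                    })
      eta <- f$coefficients[1] +
        sum(f$coefficients[-1] * as.numeric(X[i, terms]))
      if (transform == "log") exp(eta) else eta
    }
  }, 0)
  full <- fit_ols(yt, X[, terms, drop = FALSE])
  cv_r2 <- stats::cor(y, pred)^2
  sse <- sum((y - pred)^2)
  structure(list(
    model_r2 = full$r2, model_adj_r2 = full$adj_r2,
    cv_r2 = cv_r2,
    cv_r2_ss = 1 - sse / sum((y - mean(y))^2),
    r2_gap = r2_gap(full$r2, cv_r2),
    cv_mse = sse / n, cv_sse = sse,
    pairs = data.frame(observed = y, predicted = pred),
    terms = terms, transform = transform, n = n),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> n = %d, model R2 = %.3f, CV R2 = %.3f (gap %d pp)\n",
              x$n, x$model_r2, x$cv_r2, x$r2_gap))
  cat(sprintf("  CV mean squared error %.4g (sum %.4g)\n", x$cv_mse, x$cv_sse))
  invisible(x)
}

#' Model-vs-validation R2 difference in percentage points
#'
#' The reporting convention for LUR stability: the absolute difference
#' between the model R2 and the cross-validation R2, in rounded integer
#' percentage points.
#'
#' @param model_r2,cv_r2 R2 values in [0, 1].
#' @return Integer percentage points.
#' @export
r2_gap <- function(model_r2, cv_r2) {
  stopifnot(model_r2 >= 0, model_r2 <= 1, cv_r2 >= 0, cv_r2 <= 1)
  as.integer(round(100 * abs(model_r2 - cv_r2)))
}

#' Bland-Altman agreement between paired measurements
#'
#' @param a,b paired measurement vectors (e.g. sampler vs. reference
#'   station), at least 2 pairs.
#' @return An \code{agreement_summary}: mean difference, SD of the
#'   differences (n - 1 denominator), 95% limits of agreement
#'   d_bar +/- 1.96 SD, and n.
#' @export
bland_altman <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) < 2) stop("Bland-Altman needs at least 2 pairs")
  d <- a - b
  dbar <- mean(d)
  sdd <- stats::sd(d)
  structure(list(mean_difference = dbar, sd_difference = sdd,
                 lower_limit = dbar - 1.96 * sdd,
                 upper_limit = dbar + 1.96 * sdd,
                 n = length(a),
                 means = (a + b) / 2, differences = d),
            class = "agreement_summary")
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf("<agreement_summary> n = %d: mean difference %.3f, limits (%.3f, %.3f)\n",
              x$n, x$mean_difference, x$lower_limit, x$upper_limit))
  invisible(x)
}
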