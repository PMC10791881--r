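#' LUR model objects, screening, and supervised selection
#'
#' The statistical core of the package: a spatial multivariable regression
#' Z(x_i, y_i) = b0 + sum_j b_j Z_j(x_i, y_i) + e, e ~ N(0, v^2), fitted by
#' OLS on buffer predictors after two screening rules (pairwise correlation
#' above 0.7 and zero values at more than 90% of sites), with supervised
#' selection that retains only terms that are statistically significant
#' (p < 0.05), carry the theoretically expected coefficient sign, and do
#' not inflate variance (VIF cap).
#'
#' @name lurfit
NULL

#' Construct a LUR model
#'
#' @param pollutant pollutant label (e.g. "PM2.5", "NO2").
#' @param transform "identity" or "log" (the model is fitted on log
#'   concentrations and predictions are back-transformed with exp()).
#' @param intercept numeric intercept b0.
#' @param terms data frame with \code{predictor} and \code{coefficient}
#'   columns (may have 0 rows); predictor names must be unique.
#' @param diagnostics optional list (adj_r2, r2, rmse, max_vif, n_sites).
#' @return A \code{lur_model}.
#' @export
lur_model <- function(pollutant, transform = c("identity", "log"),
                      intercept, terms = data.frame(predictor = character(0),
                                                    coefficient = numeric(0)),
                      diagnostics = NULL) {
  transform <- match.arg(transform)
  terms <- data.frame(predictor = as.character(terms$predictor),
                      coefficient = as.numeric(terms$coefficient),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(terms$predictor)) stop("duplicate term predictor names")
  structure(list(pollutant = pollutant, transform = transform,
                 intercept = as.numeric(intercept), terms = terms,
                 diagnostics = diagnostics),
            class = "lur_model")
}

#' @export
print.lur_model <- function(x, ...) {
  cat("<lur_model>", format_model_equation(x), "\n")
  d <- x$diagnostics
  if (!is.null(d)) {
    cat(sprintf("  n = %s, adj R2 = %.3f, RMSE = %.3f (%s scale), max VIF = %s\n",
                d$n_sites, d$adj_r2, d$rmse, x$transform,
                ifelse(is.null(d$max_vif) || is.na(d$max_vif), "-",
                       sprintf("%.2f", d$max_vif))))
  }
  invisible(x)
}

#' Evaluate a LUR model on a predictor record
#'
#' @param object a \code{lur_model}.
#' @param newdata data frame (or named list) holding every predictor the
#'   model's terms reference; missing names are an error, never a silent
#'   zero-fill.
#' @param ... unused.
#' @return Predicted concentration(s); exp(eta) for log-transform models.
#' @export
predict.lur_model <- function(object, newdata, ...) {
  need <- object$terms$predictor
  missing <- setdiff(need, names(newdata))
  if (length(missing) > 0) {
    stop("predictors missing from record: ", paste(missing, collapse = ", "))
  }
  eta <- object$intercept
  for (i in seq_len(nrow(object$terms))) {
    eta <- eta + object$terms$coefficient[i] * newdata[[need[i]]]
  }
  if (length(eta) == 0) eta <- object$intercept
  if (object$transform == "log") exp(eta) else eta
}

.numeric_predictors <- function(table) {
  keep <- setdiff(names(table), "site_id")
  keep <- keep[vapply(table[keep], is.numeric, TRUE)]
  table[keep]
}

#' Screen predictors by zero-fraction and pairwise correlation
#'
#' The zero-fraction rule is applied first: columns whose zero values
#' account for more than \code{zero_frac} of the sites are removed. Then
#' pairs with |r| > \code{r_max} are pruned iteratively in descending |r|;
#' within a pair the member with the weaker absolute correlation to the
#' outcome is dropped. Columns containing NA sentinels or with zero
#' variance are removed up front (they cannot enter a regression).
#'
#' @param table predictor table (a \code{site_id} column is carried
#'   through untouched).
#' @param y outcome vector aligned with the table rows.
#' @param r_max pairwise correlation threshold (default 0.7).
#' @param zero_frac zero-fraction threshold (default 0.9).
#' @return List with \code{table} (reduced) and \code{log} (data frame
#'   \code{name, reason, detail}); removed + retained = input columns.
#' @export
screen_predictors <- function(table, y, r_max = 0.7, zero_frac = 0.9) {
  stopifnot(r_max > 0, r_max < 1)
  X <- .numeric_predictors(table)
  if (nrow(X) != length(y)) stop("table rows do not align with y")
  if (stats::sd(y) == 0) stop("outcome is constant; nothing to screen against")
  log_rows <- list()
  note <- function(name, reason, detail = "") {
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      name = name, reason = reason, detail = detail, stringsAsFactors = FALSE)
  }
  if (ncol(X) >= 1) {
    has_na <- names(X)[vapply(X, anyNA, TRUE)]
    for (nm in has_na) note(nm, "missing", "NA sentinel values")
    X <- X[setdiff(names(X), has_na)]
    zf <- vapply(X, function(v) mean(v == 0), 0)
    for (nm in names(zf)[zf > zero_frac]) {
      note(nm, "zero_fraction", sprintf("fraction %.3f > %.2f",
                                        zf[nm], zero_frac))
    }
    X <- X[names(zf)[zf <= zero_frac]]
    cst <- names(X)[vapply(X, function(v) stats::sd(v) == 0, TRUE)]
    for (nm in cst) note(nm, "constant", "zero variance")
    X <- X[setdiff(names(X), cst)]
  }
  if (ncol(X) >= 2) {
    repeat {
      cm <- abs(stats::cor(X))
      diag(cm) <- 0
      top <- which(cm == max(cm), arr.ind = TRUE)[1, ]
      if (cm[top[1], top[2]] <= r_max) break
      a <- colnames(cm)[top[1]]; b <- colnames(cm)[top[2]]
      ra <- abs(stats::cor(X[[a]], y)); rb <- abs(stats::cor(X[[b]], y))
      # drop the weaker outcome-correlate; on exact ties (e.g. the
      # definitionally proportional POB/DEN pair) drop the earlier column
      # so the decision is deterministic, not floating-point noise
      if (abs(ra - rb) < 1e-10) {
        first <- which(names(X) %in% c(a, b))[1]
        drop_nm <- names(X)[first]
        keep_nm <- setdiff(c(a, b), drop_nm)
      } else {
        drop_nm <- if (ra < rb) a else b
        keep_nm <- if (ra < rb) b else a
      }
      note(drop_nm, "correlation",
           sprintf("|r| = %.4f with %s", cm[top[1], top[2]], keep_nm))
      X <- X[setdiff(names(X), drop_nm)]
      if (ncol(X) < 2) break
    }
  }
  log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(name = character(0), reason = character(0),
               detail = character(0), stringsAsFactors = FALSE)
  out <- if ("site_id" %in% names(table)) {
    cbind(table["site_id"], X)
  } else X
  list(table = out, log = log)
}

#' Ordinary least squares with LUR diagnostics
#'
#' Standard OLS of y on the columns of X with an intercept. Reports
#' two-sided t-test p-values, adjusted R2 = 1 - (1 - R2)(n - 1)/(n - p - 1),
#' and RMSE = sqrt(SSE / (n - p - 1)) on the modelled scale.
#'
#' @param y outcome vector.
#' @param X data frame or matrix of predictors (no intercept column); may
#'   have zero columns for an intercept-only fit.
#' @return List with \code{coefficients} (incl. "(Intercept)"),
#'   \code{p_values}, \code{r2}, \code{adj_r2}, \code{rmse}, \code{n},
#'   \code{p}, and the underlying \code{lm} fit.
#' @export
fit_ols <- function(y, X) {
  X <- as.data.frame(X)
  n <- length(y); p <- ncol(X)
  if (n != max(nrow(X), n)) stop("X rows do not match y")
  if (p > 0 && nrow(X) != n) stop("X rows do not match y")
  if (n - p - 1 <= 0) {
    stop("n - p - 1 <= 0: too many predictors (", p, ") for ", n,
         " sites; adjusted R2 is undefined")
  }
  dat <- if (p > 0) cbind(.y = y, X) else data.frame(.y = y)
  form <- if (p > 0) stats::reformulate(sprintf("`%s`", names(X)), ".y") else
    stats::as.formula(".y ~ 1")
  fit <- stats::lm(form, data = dat)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    bad <- gsub("`", "", names(cf)[is.na(cf)])
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  names(cf) <- gsub("`", "", names(cf))
  pv <- sm$coefficients[, 4]
  names(pv) <- gsub("`", "", names(pv))
  se <- sm$coefficients[, 2]
  names(se) <- gsub("`", "", names(se))
  list(coefficients = cf, p_values = pv, se = se, df = n - p - 1, r2 = r2,
       adj_r2 = if (is.na(r2)) NA_real_ else
         1 - (1 - r2) * (n - 1) / (n - p - 1),
       rmse = sqrt(sse / (n - p - 1)), n = n, p = p, fit = fit)
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R2_j) where R2_j regresses column j on the remaining
#' columns (with intercept). Perfectly collinear columns are reported as
#' Inf and flagged via the "flagged" attribute.
#'
#' @param X data frame or matrix with at least two columns.
#' @return Named vector of VIFs.
#' @export
vif <- function(X) {
  X <- as.data.frame(X)
  if (ncol(X) < 2) stop("VIF needs at least two columns")
  out <- vapply(seq_along(X), function(j) {
    fit <- stats::lm(X[[j]] ~ ., data = X[-j])
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
  names(out) <- names(X)
  if (any(is.infinite(out))) {
    attr(out, "flagged") <- names(out)[is.infinite(out)]
  }
  out
}

#' Supervised sign-constrained model selection
#'
#' Selects a LUR model in which every retained term is significant
#' (p < alpha), has a coefficient sign consistent with its expected
#' theoretical direction (unless "either"), and the design's maximum VIF
#' does not exceed \code{vif_max}. Two modes:
#' \describe{
#'   \item{prune}{(default) start from all screened predictors, then
#'     iteratively drop the worst violator -- first wrong-sign terms
#'     (largest p), then the largest VIF above the cap, then the least
#'     significant term -- refitting after each drop.}
#'   \item{forward}{supervised forward search: repeatedly add the
#'     predictor giving the largest adjusted-R2 gain among additions that
#'     keep every coefficient sign-consistent, while the gain exceeds
#'     0.01; then prune non-significant and high-VIF terms as above.}
#' }
#' When more predictors survive screening than the sample can support,
#' the starting set is capped at n - 5 columns ranked by absolute
#' correlation with the outcome (logged). If no predictor survives, an
#' intercept-only model is returned with a warning.
#'
#' @param table screened predictor table.
#' @param y observed concentrations.
#' @param signs expected-sign table (see \code{\link{expected_signs}}).
#' @param alpha significance level for the two-sided t-tests.
#' @param vif_max maximum tolerated VIF.
#' @param transform "identity" or "log" (log models are fitted on log(y),
#'   which must be positive).
#' @param mode "prune" or "forward".
#' @param pollutant label stored on the returned model.
#' @return A \code{lur_model} with diagnostics; the selection path is
#'   attached as attribute "path".
#' @export
supervised_select <- function(table, y, signs = expected_signs(),
                              alpha = 0.05, vif_max = 5,
                              transform = c("identity", "log"),
                              mode = c("prune", "forward"),
                              pollutant = "PM2.5") {
  transform <- match.arg(transform)
  mode <- match.arg(mode)
  X <- .numeric_predictors(table)
  if (transform == "log") {
    if (any(y <= 0)) stop("log transform requires positive concentrations")
    yt <- log(y)
  } else yt <- y
  n <- length(yt)
  path <- list()
  step <- function(action, name, why) {
    path[[length(path) + 1L]] <<- data.frame(action = action, name = name,
                                             why = why,
                                             stringsAsFactors = FALSE)
  }
  exp_sign <- sign_for(names(X), signs)

  # keep the events-per-variable ratio of the working set sane: an
  # all-in fit with p approaching n produces meaningless signs and
  # p-values, so the starting set is capped at n/2 columns ranked by
  # absolute correlation with the outcome
  cap <- max(min(n - 5L, floor(n / 2)), 1L)
  if (mode == "prune" && ncol(X) > cap) {
    ord <- order(-abs(vapply(X, function(v) stats::cor(v, yt), 0)))
    dropped <- names(X)[ord[-seq_len(cap)]]
    for (nm in dropped) step("cap", nm, "starting set capped at n/2")
    X <- X[names(X)[ord[seq_len(cap)]]]
    exp_sign <- exp_sign[names(X)]
  }

  sign_ok <- function(cf) {
    es <- exp_sign[names(cf)]
    (es == "either") | (es == "+" & cf > 0) | (es == "-" & cf < 0)
  }

  if (mode == "forward") {
    sel <- character(0)
    best_adj <- -Inf
    repeat {
      cands <- setdiff(names(X), sel)
      if (length(cands) == 0 || length(sel) >= n - 3) break
      gains <- vapply(cands, function(nm) {
        if (length(sel) + 1 >= n - 1) return(-Inf)
        f <- tryCatch(fit_ols(yt, X[c(sel, nm)]), error = function(e) NULL)
        if (is.null(f)) return(-Inf)
        cf <- f$coefficients[-1]
        if (!all(sign_ok(cf))) return(-Inf)
        f$adj_r2
      }, 0)
      if (all(!is.finite(gains))) break
      top <- names(gains)[which.max(gains)]
      if (max(gains) - max(best_adj, 0) <= 0.01 && length(sel) > 0) break
      if (!is.finite(max(gains))) break
      sel <- c(sel, top)
      best_adj <- max(gains)
      step("add", top, sprintf("adj R2 -> %.4f", best_adj))
    }
    X <- X[sel]
  }

  # iterative pruning (also the cleanup stage of the forward mode)
  repeat {
    if (ncol(X) == 0) break
    f <- tryCatch(fit_ols(yt, X), error = function(e) e)
    if (inherits(f, "error")) {
      # jointly collinear set that survived pairwise screening (e.g.
      # compositional land-use fractions): drop the named column
      m <- regmatches(conditionMessage(f),
                      regexec("collinear columns: (\\S+)", conditionMessage(f)))[[1]]
      if (length(m) < 2) stop(f)
      step("drop", m[2], "collinear with retained columns")
      X <- X[setdiff(names(X), m[2])]
      next
    }
    cf <- f$coefficients[-1]
    pv <- f$p_values[-1]
    ok_sign <- sign_ok(cf)
    vifs <- if (ncol(X) >= 2) vif(X) else stats::setNames(1, names(X))
    if (any(!ok_sign)) {
      bad <- names(cf)[!ok_sign]
      drop_nm <- bad[which.max(pv[bad])]
      step("drop", drop_nm, sprintf("sign %+.3g conflicts with expected %s",
                                    cf[drop_nm], exp_sign[drop_nm]))
    } else if (any(pv >= alpha)) {
      drop_nm <- names(pv)[which.max(pv)]
      step("drop", drop_nm, sprintf("p = %.4f >= %.3f", pv[drop_nm], alpha))
    } else if (max(vifs) > vif_max) {
      # multicollinearity is judged on the final candidate model, the
      # set the VIFs are reported for, not on the full working soup
      drop_nm <- names(vifs)[which.max(vifs)]
      step("drop", drop_nm, sprintf("VIF %.2f > %.2f", max(vifs), vif_max))
    } else break
    X <- X[setdiff(names(X), drop_nm)]
  }

  if (ncol(X) == 0) {
    warning("no predictor survived supervised selection; ",
            "returning an intercept-only model")
    f <- fit_ols(yt, X)
  } else {
    f <- fit_ols(yt, X)
  }
  cf <- f$coefficients
  terms <- data.frame(predictor = names(cf)[-1],
                      coefficient = unname(cf[-1]),
                      stringsAsFactors = FALSE)
  model <- lur_model(pollutant, transform, cf[1], terms,
                     diagnostics = list(
                       adj_r2 = f$adj_r2, r2 = f$r2, rmse = f$rmse,
                       max_vif = if (ncol(X) >= 2) max(vif(X)) else NA_real_,
                       n_sites = f$n,
                       p_values = f$p_values,
                       se = f$se, df = f$df))
  attr(model, "path") <- if (length(path)) do.call(rbind, path) else
    data.frame(action = character(0), name = character(0),
               why = character(0), stringsAsFactors = FALSE)
  model
}
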