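#' Replicate studies: parameter recovery and form selection
#'
#' The package's evidence that the pipeline works does not come from the
#' field data (which is not redistributable) but from seeded replicate
#' studies on synthetic cities: if buffer extraction, screening, and
#' sign-constrained selection are correct, the generating coefficients
#' must be recovered within their confidence intervals, and pure-noise
#' predictors must enter the selected model at no more than the nominal
#' type-I rate.
#'
#' @name experiments
NULL

#' Parameter-recovery study over seeded synthetic cities
#'
#' Each replicate generates a city and stratified sites, simulates
#' two-campaign measurements from a fixed 3-term ground-truth model with
#' weekly noise equal to \code{noise_frac} of the signal SD, appends
#' \code{n_noise} pure-noise predictors, and runs the full
#' screening + supervised-selection pipeline. A true coefficient is
#' "recovered" when its predictor is selected and the generating value
#' lies inside the fitted 95% confidence interval.
#'
#' @param n_reps number of seeded replicates.
#' @param n_sites monitoring sites per city.
#' @param noise_frac weekly noise SD as a fraction of the signal SD.
#' @param n_noise pure-noise N(0, 1) predictors appended per replicate.
#' @param alpha selection significance level.
#' @param mode selection mode; the supervised forward search is the
#'   appropriate configuration when candidate predictors outnumber
#'   sites, keeping the working model small relative to n.
#' @param seed base seed; replicate r uses seed + r.
#' @return List: \code{recovery} (per-coefficient recovery fraction),
#'   \code{selected} (per-coefficient selection fraction),
#'   \code{noise_rate} (per-noise-predictor inclusion fraction),
#'   \code{noise_terms_per_rep} (mean count), and the per-replicate
#'   detail table.
#' @export
recovery_experiment <- function(n_reps = 100, n_sites = 40,
                                noise_frac = 0.10, n_noise = 10,
                                alpha = 0.05, mode = "forward", seed = 1) {
  truth_terms <- default_config()$true_terms
  true_b <- stats::setNames(truth_terms$coefficient, truth_terms$predictor)
  rows <- lapply(seq_len(n_reps), function(r) {
    s <- seed + r
    city <- generate_city(seed = s)
    sites <- generate_sites(city, n_sites, seed = s + 10000L)
    ptab <- build_predictor_table(city, sites, quiet = TRUE)
    true_model <- lur_model("PM2.5", "identity",
                            default_config()$true_intercept, truth_terms)
    signal <- predict(true_model, ptab)
    truth <- ground_truth_field(true_model, noise_frac * stats::sd(signal))
    meas <- simulate_measurements(city, truth, sites,
                                  campaign_offsets = c(1, -1),
                                  seed = s + 20000L, predictors = ptab)
    y <- annual_means(meas)$means$annual
    noise_cols <- withr::with_seed(s + 30000L, {
      as.data.frame(matrix(stats::rnorm(n_sites * n_noise), n_sites,
                           dimnames = list(NULL, paste0("ZNOISE",
                                                        seq_len(n_noise)))))
    })
    tab <- cbind(ptab, noise_cols)
    screened <- screen_predictors(tab, y)
    model <- suppressWarnings(supervised_select(screened$table, y,
                                                alpha = alpha, mode = mode))
    sel <- model$terms$predictor
    d <- model$diagnostics
    tcrit <- stats::qt(0.975, d$df)
    in_ci <- vapply(names(true_b), function(nm) {
      if (!nm %in% sel) return(FALSE)
      b <- model$terms$coefficient[model$terms$predictor == nm]
      se <- d$se[nm]
      abs(b - true_b[nm]) <= tcrit * se
    }, TRUE)
    c(stats::setNames(as.numeric(names(true_b) %in% sel),
                      paste0("sel_", names(true_b))),
      stats::setNames(as.numeric(in_ci), paste0("ci_", names(true_b))),
      n_noise_in = sum(grepl("^ZNOISE", sel)))
  })
  detail <- as.data.frame(do.call(rbind, rows))
  list(recovery = colMeans(detail[paste0("ci_", names(true_b))]),
       selected = colMeans(detail[paste0("sel_", names(true_b))]),
       noise_rate = mean(detail$n_noise_in) / n_noise,
       noise_terms_per_rep = mean(detail$n_noise_in),
       true_coefficients = true_b,
       detail = detail)
}

#' Form-selection study for speed-density fitting
#'
#' Generates noisy observations from a known functional form and counts
#' how often RMSE-based selection over all six candidates recovers it.
#'
#' @param n_reps number of seeded replicates.
#' @param form generating form.
#' @param parameters generating parameters.
#' @param n_obs observations per replicate.
#' @param noise_sd speed noise SD (km/h).
#' @param n_resamples bootstrap resamples per candidate form.
#' @param seed base seed.
#' @return List with \code{rate} (fraction of replicates selecting the
#'   generating form) and the per-replicate selected forms.
#' @export
form_selection_experiment <- function(n_reps = 100, form = "greenshields",
                                      parameters = c(vf = 60, kj = 120),
                                      n_obs = 200, noise_sd = 2,
                                      n_resamples = 25, seed = 1) {
  picked <- vapply(seq_len(n_reps), function(r) {
    obs <- simulate_flow_observations(form, parameters, n = n_obs,
                                      noise_sd = noise_sd, seed = seed + r)
    m <- suppressWarnings(fit_flow_model(obs, n_resamples = n_resamples,
                                         seed = seed + 50000L + r))
    m$form
  }, "")
  list(rate = mean(picked == form), selected = picked)
}
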