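#' Published LUR models for five Colombian cities
#'
#' The annual PM2.5 and NO2 LUR models published for Barranquilla, Bogota,
#' Bucaramanga, Cali and Medellin (2021 measurement campaigns), with their
#' printed fit statistics. Equations are stored verbatim in the printed
#' dialect (en-dash minus signs, Unicode asterisk multiplication,
#' inconsistent spacing) and are parseable with
#' \code{\link{parse_model_equation}}; they serve as worked examples for
#' the equation parser/evaluator and for the reporting arithmetic
#' (\code{\link{r2_gap}}).
#'
#' Note the printed variable dialect: DTRON is the distance to the trunk
#' roadway, and WPROM (mean wind speed) appears in one model although the
#' variable catalogue lists wind direction (WD); both are carried in the
#' package's catalogue.
#'
#' @return Data frame with \code{city, pollutant, equation, n_sites,
#'   model_r2, rmse, max_vif, cv_r2}.
#' @export
published_lur_models <- function() {
  # \u2013 en dash (printed minus), \u2217 asterisk operator
  data.frame(
    city = rep(c("Barranquilla", "Bogot\u00e1", "Bucaramanga", "Cali",
                 "Medell\u00edn"), 2),
    pollutant = rep(c("PM2.5", "NO2"), each = 5),
    equation = c(
      paste0("PM_2.5_ = 19.83344\u20130.1489524*ALT\u20130.0230902*DTRON500",
             " + 44.43591*IND200 + 21.93109*CEN500 + 23.10317*PORT500"),
      paste0("Ln (PM_2.5_) = 2.4713 + 3.1439*DEN100 + ",
             "1.8045*IND200\u20130.8418*RES500"),
      paste0("Ln (PM_2.5_) = 2.199057 + 0.0014062 \u2217 SEC100 + ",
             "0.0000327 \u2217 LOC500\u20130.0012659 \u2217 DPRIM500 + ",
             "0.0215501 \u2217 VEL100\u20130.000242 \u2217 VOL200"),
      paste0("Ln (PM_2.5_) = 2.3387 + 0.00001 \u2217 DOT200 + ",
             "1.0713 \u2217 PRIM200 + 0.5943 \u2217 SEC200\u2013",
             "0.0004 \u2217 VOL100"),
      paste0("PM_2.5_ = 13.77207\u20131.357455 \u2217 PPROM\u2013",
             "5.589831 \u2217 DOT100 + 2.269679 \u2217 DEN200 + ",
             "70.23039 \u2217 MIX500 + 0.0043842 \u2217 VOL500"),
      paste0("NO_2_ = 12.89591 + 25.45936 \u2217 PRIM100\u2013",
             "0.1583713 \u2217 VEL100 + 0.0061518 \u2217 VOL500"),
      "Ln (NO_2_) = 2.8714 + 0.0001*PRIM500 + 0.0058*VEL100 + 0.2599*WPROM",
      paste0("NO_2_ = 13.00243 + 291.5302 \u2217 DEN100\u2013",
             "0.0013283 \u2217 POB500 + 0.0025503 \u2217 TER500 + ",
             "0.0020514 \u2217 LOC500 + 0.0057464 \u2217 VOL100"),
      paste0("Ln (NO_2_) = 3.47834312 + 0.49126931*PRIM200 + ",
             "0.39823891 \u2217 SEC200 + 0.36505469 \u2217 TER200\u2013",
             "0.01475995 \u2217 VEL200"),
      paste0("NO_2_ = 46.06516\u20133.625967 \u2217 PPROM\u2013",
             "0.0299678 \u2217 DSEC200 + 0.0225605 \u2217 VOL500")),
    n_sites = c(20L, 40L, 20L, 17L, 19L, 36L, 73L, 40L, 40L, 34L),
    model_r2 = c(0.73, 0.44, 0.77, 0.70, 0.82, 0.30, 0.40, 0.65, 0.44, 0.57),
    rmse = c(3.98, 1.39, 1.23, 1.28, 1.71, 8.02, 1.26, 8.08, 1.28, 5.53),
    max_vif = c(1.90, 1.63, 1.78, 2.06, 1.48, 1.28, 1.19, 1.66, 1.56, 1.06),
    cv_r2 = c(0.54, 0.38, 0.46, 0.51, 0.79, 0.19, 0.34, 0.55, 0.36, 0.45),
    stringsAsFactors = FALSE)
}
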