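#' Parse and serialise printed LUR equations
#'
#' Published LUR tables print fitted equations in a compact dialect:
#' an optional "Ln (...)" prefix marking a log-transform model, signed
#' terms "coef * NAME" with the multiplication sign written as "*" or
#' "\u2217", and minus signs that may be ASCII hyphens, en dashes
#' ("\u2013") or Unicode minus ("\u2212"), with inconsistent spacing.
#' \code{parse_model_equation} reads that dialect losslessly into a
#' \code{\link{lur_model}}; \code{format_model_equation} writes the
#' canonical ASCII form, and parse -> serialise -> parse is the identity.
#'
#' @name equations
NULL

.normalise_equation <- function(text) {
  text <- gsub("\u2013|\u2212|\u2014", "-", text)
  text <- gsub("\u2217|\u00d7", "*", text)
  gsub("[[:space:]\u00a0]+", "", text)
}

# shortest decimal representation that survives a numeric round-trip
.fmt_num <- function(x) {
  for (d in c(15L, 16L, 17L)) {
    s <- trimws(formatC(x, format = "g", digits = d))
    if (as.numeric(s) == x) return(s)
  }
  s
}

#' Parse a printed LUR equation
#'
#' @param text equation string, e.g.
#'   \code{"PM_2.5_ = 19.83344 - 0.1489524*ALT + 44.43591*IND200"} or the
#'   log form \code{"Ln (NO_2_) = 2.8714 + 0.0001*PRIM500"}.
#' @return A \code{lur_model} with \code{transform = "log"} iff the
#'   Ln-prefix is present; the left-hand-side label is kept as the
#'   pollutant.
#' @export
parse_model_equation <- function(text) {
  s <- .normalise_equation(text)
  eq <- regexpr("=", s, fixed = TRUE)
  if (eq < 0) stop("no '=' found in equation")
  lhs <- substr(s, 1, eq - 1)
  rhs <- substr(s, eq + 1, nchar(s))
  if (nchar(rhs) == 0) stop("empty right-hand side at character ", eq + 1)
  ln <- regmatches(lhs, regexec("^[Ll][Nn]\\((.+)\\)$", lhs))[[1]]
  transform <- if (length(ln) == 2) "log" else "identity"
  pollutant <- if (length(ln) == 2) ln[2] else lhs
  if (nchar(pollutant) == 0) stop("empty left-hand side")

  term_re <- "^([+-]?)([0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?)(?:\\*([A-Za-z][A-Za-z0-9_.]*))?"
  pos <- 1
  intercept <- 0
  has_intercept <- FALSE
  preds <- character(0); coefs <- numeric(0)
  rest <- rhs
  while (nchar(rest) > 0) {
    m <- regexec(term_re, rest)[[1]]
    if (m[1] < 0) {
      stop("malformed term at character ", eq + pos, " of equation: '",
           substr(rest, 1, 12), "'")
    }
    g <- regmatches(rest, regexec(term_re, rest))[[1]]
    val <- as.numeric(paste0(ifelse(g[2] == "-", "-", ""), g[3]))
    if (nchar(g[4]) > 0) {
      preds <- c(preds, g[4]); coefs <- c(coefs, val)
    } else {
      intercept <- intercept + val
      has_intercept <- TRUE
    }
    len <- attr(m, "match.length")[1]
    rest <- substr(rest, len + 1, nchar(rest))
    pos <- pos + len
  }
  if (!has_intercept && length(preds) == 0) {
    stop("equation has no terms")
  }
  if (anyDuplicated(preds)) {
    stop("duplicate predictor in equation: ",
         paste(unique(preds[duplicated(preds)]), collapse = ", "))
  }
  lur_model(pollutant, transform, intercept,
            data.frame(predictor = preds, coefficient = coefs,
                       stringsAsFactors = FALSE))
}

#' Serialise a LUR model to the canonical ASCII equation
#'
#' @param model a \code{lur_model}.
#' @return A string such as
#'   \code{"Ln(NO_2_) = 2.8714 + 0.0001*PRIM500"}; parsing it back yields
#'   an identical model.
#' @export
format_model_equation <- function(model) {
  lhs <- if (model$transform == "log") {
    paste0("Ln(", model$pollutant, ")")
  } else model$pollutant
  out <- paste0(lhs, " = ", .fmt_num(model$intercept))
  for (i in seq_len(nrow(model$terms))) {
    b <- model$terms$coefficient[i]
    out <- paste0(out, ifelse(b < 0, " - ", " + "), .fmt_num(abs(b)), "*",
                  model$terms$predictor[i])
  }
  out
}

#' Write / read a LUR model as JSON
#'
#' @param model a \code{lur_model}.
#' @param path file path.
#' @export
write_lur_model <- function(model, path) {
  obj <- list(pollutant = model$pollutant, transform = model$transform,
              intercept = model$intercept,
              terms = model$terms, diagnostics = model$diagnostics,
              equation = format_model_equation(model))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lur_model
#' @export
read_lur_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lur_model(obj$pollutant, obj$transform, obj$intercept,
            as.data.frame(obj$terms), obj$diagnostics)
}
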