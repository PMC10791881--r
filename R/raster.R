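#' Minimal in-memory raster in a projected metric CRS
#'
#' A \code{lur_raster} stores a value matrix with row 1 at the *bottom* of
#' the extent (y increasing with row index, x increasing with column index),
#' plus the lower-left corner and square cell size in metres. ESRI ASCII
#' grid is used for on-disk interchange.
#'
#' @param values numeric matrix (rows = y from bottom, cols = x from left).
#' @param xmin,ymin lower-left corner of the extent (m).
#' @param cellsize square cell edge (m).
#' @return A \code{lur_raster} object.
#' @export
lur_raster <- function(values, xmin = 0, ymin = 0, cellsize = 50) {
  stopifnot(is.matrix(values), cellsize > 0)
  structure(list(values = values, xmin = xmin, ymin = ymin,
                 cellsize = cellsize),
            class = "lur_raster")
}

#' @export
print.lur_raster <- function(x, ...) {
  cat(sprintf("<lur_raster> %d x %d cells of %g m, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$xmin, x$ymin))
  cat(sprintf("  values: [%g, %g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Raster extent as c(xmin, ymin, xmax, ymax)
#' @param r a \code{lur_raster}.
#' @export
raster_extent <- function(r) {
  c(r$xmin, r$ymin,
    r$xmin + ncol(r$values) * r$cellsize,
    r$ymin + nrow(r$values) * r$cellsize)
}

#' Cell-centre coordinates of a raster
#' @param r a \code{lur_raster}.
#' @return List with vectors \code{x} (columns) and \code{y} (rows).
#' @export
raster_centres <- function(r) {
  list(x = r$xmin + (seq_len(ncol(r$values)) - 0.5) * r$cellsize,
       y = r$ymin + (seq_len(nrow(r$values)) - 0.5) * r$cellsize)
}

#' Value of the cell containing each point
#'
#' @param r a \code{lur_raster}.
#' @param x,y point coordinates (vectors, m).
#' @return Vector of cell values; NA outside the extent.
#' @export
raster_value_at <- function(r, x, y) {
  cj <- floor((x - r$xmin) / r$cellsize) + 1L
  ci <- floor((y - r$ymin) / r$cellsize) + 1L
  # points exactly on the top/right boundary belong to the last cell
  cj[x == r$xmin + ncol(r$values) * r$cellsize] <- ncol(r$values)
  ci[y == r$ymin + nrow(r$values) * r$cellsize] <- nrow(r$values)
  ok <- ci >= 1L & ci <= nrow(r$values) & cj >= 1L & cj <= ncol(r$values)
  out <- rep(NA_real_, length(x))
  out[ok] <- r$values[cbind(ci[ok], cj[ok])]
  out
}

#' Write a raster as an ESRI ASCII grid
#'
#' @param r a \code{lur_raster}.
#' @param path output file.
#' @export
write_ascii_grid <- function(r, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(r$values)),
    sprintf("nrows %d", nrow(r$values)),
    sprintf("xllcorner %.10g", r$xmin),
    sprintf("yllcorner %.10g", r$ymin),
    sprintf("cellsize %.10g", r$cellsize),
    "NODATA_value -9999"), con)
  # ASCII grids are written top row first
  for (i in rev(seq_len(nrow(r$values)))) {
    writeLines(paste(format(r$values[i, ], trim = TRUE, digits = 10),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid written by \code{write_ascii_grid}
#'
#' @param path input file.
#' @return A \code{lur_raster}.
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(trimws(hdr), "\\s+")
  key <- tolower(vapply(kv, `[`, "", 1))
  val <- as.numeric(vapply(kv, `[`, "", 2))
  names(val) <- key
  body <- utils::read.table(path, skip = 6)
  m <- as.matrix(body)
  dimnames(m) <- NULL
  m[m == val["nodata_value"]] <- NA_real_
  lur_raster(m[rev(seq_len(nrow(m))), , drop = FALSE],
             xmin = unname(val["xllcorner"]), ymin = unname(val["yllcorner"]),
             cellsize = unname(val["cellsize"]))
}
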