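#' Lightweight geographic raster
#'
#' A minimal single-band raster on a regular lon/lat grid: a numeric matrix
#' whose first row is the northernmost row, plus the georeference of the grid
#' (lower-left corner and square cell size in degrees). All stacks produced by
#' the package share one grid, so layer algebra reduces to matrix algebra.
#'
#' @param values numeric matrix; row 1 is the northern edge.
#' @param xmin,ymin longitude/latitude of the lower-left corner (degrees).
#' @param cellsize cell size in degrees (square cells).
#' @param nodata value used to mark missing cells on disk; in memory `NA`.
#' @return an object of class `mr_raster`.
#' @export
mr_raster <- function(values, xmin, ymin, cellsize, nodata = -9999) {
  stopifnot(is.matrix(values), is.numeric(cellsize), cellsize > 0)
  structure(list(values = values, xmin = xmin, ymin = ymin,
                 cellsize = cellsize, nodata = nodata),
            class = "mr_raster")
}

#' @export
print.mr_raster <- function(x, ...) {
  cat(sprintf("mr_raster: %d x %d cells, %.4g deg, origin (%.3f, %.3f)\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$xmin, x$ymin))
  invisible(x)
}

raster_ymax <- function(r) r$ymin + nrow(r$values) * r$cellsize

#' Cell-center latitudes (north to south) and longitudes (west to east)
#' @param r an `mr_raster`.
#' @export
raster_lats <- function(r) raster_ymax(r) - (seq_len(nrow(r$values)) - 0.5) * r$cellsize

#' @rdname raster_lats
#' @export
raster_lons <- function(r) r$xmin + (seq_len(ncol(r$values)) - 0.5) * r$cellsize

same_grid <- function(a, b, tol = 1e-9) {
  all(dim(a$values) == dim(b$values)) &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymin - b$ymin) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

#' Map coordinates to cell indices
#'
#' @param r an `mr_raster`.
#' @param lat,lon coordinate vectors (degrees).
#' @return a two-column matrix of (row, col); NA where outside the grid.
#' @export
raster_cell_of <- function(r, lat, lon) {
  row <- ceiling((raster_ymax(r) - lat) / r$cellsize)
  col <- ceiling((lon - r$xmin) / r$cellsize)
  row[row < 1 | row > nrow(r$values)] <- NA_integer_
  col[col < 1 | col > ncol(r$values)] <- NA_integer_
  bad <- is.na(row) | is.na(col)
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Read / write ESRI ASCII grids
#'
#' Plain-text raster exchange format: a six-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by rows from north
#' to south. Values equal to the nodata marker become `NA` on read.
#'
#' @param path file path.
#' @export
read_ascii_grid <- function(path) {
  con <- file(path, "r"); on.exit(close(con))
  hdr <- character(6)
  for (i in 1:6) hdr[i] <- readLines(con, n = 1)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  key <- tolower(kv[, 1]); val <- as.numeric(kv[, 2])
  names(val) <- key
  ncols <- as.integer(val[["ncols"]]); nrows <- as.integer(val[["nrows"]])
  nodata <- if ("nodata_value" %in% key) val[["nodata_value"]] else -9999
  body <- scan(con, what = numeric(), quiet = TRUE)
  if (length(body) != ncols * nrows)
    stop("ASCII grid body does not match header dimensions")
  m <- matrix(body, nrow = nrows, ncol = ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  mr_raster(m, xmin = val[["xllcorner"]], ymin = val[["yllcorner"]],
            cellsize = val[["cellsize"]], nodata = nodata)
}

#' @rdname read_ascii_grid
#' @param r an `mr_raster` to write.
#' @param digits significant digits retained on disk.
#' @export
write_ascii_grid <- function(r, path, digits = 9) {
  v <- r$values
  v[is.na(v)] <- r$nodata
  hdr <- c(sprintf("ncols %d", ncol(v)), sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.10g", r$xmin), sprintf("yllcorner %.10g", r$ymin),
           sprintf("cellsize %.10g", r$cellsize),
           sprintf("NODATA_value %.10g", r$nodata))
  rows <- apply(v, 1, function(z) paste(signif(z, digits), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Bilinear resampling onto a target grid
#'
#' Interpolates a source raster at the cell centers of a template grid.
#' Queries outside the source cell-center hull are clamped to the edge, so
#' no new extremes are created.
#'
#' @param src source `mr_raster`.
#' @param template `mr_raster` whose grid defines the output.
#' @return an `mr_raster` on the template grid.
#' @export
bilinear_resample <- function(src, template) {
  lats <- raster_lats(src); lons <- raster_lons(src)
  out_lat <- raster_lats(template); out_lon <- raster_lons(template)
  # source rows run north->south; work in ascending latitude for findInterval
  lat_asc <- rev(lats)
  v <- src$values[rev(seq_along(lats)), , drop = FALSE] # row 1 = south
  fy <- approx_frac(lat_asc, out_lat)
  fx <- approx_frac(lons, out_lon)
  nr <- length(out_lat); nc <- length(out_lon)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    i0 <- fy$i0[i]; i1 <- fy$i1[i]; wy <- fy$w[i]
    r0 <- v[i0, fx$i0] * (1 - fx$w) + v[i0, fx$i1] * fx$w
    r1 <- v[i1, fx$i0] * (1 - fx$w) + v[i1, fx$i1] * fx$w
    out[i, ] <- r0 * (1 - wy) + r1 * wy
  }
  mr_raster(out, template$xmin, template$ymin, template$cellsize, template$nodata)
}

# For each query q: bracketing indices into ascending grid x and the linear
# weight of the upper neighbour; clamped at the ends.
approx_frac <- function(x, q) {
  i0 <- findInterval(q, x)
  i0[i0 < 1] <- 1
  i0[i0 >= length(x)] <- length(x) - 1
  if (length(x) == 1) return(list(i0 = rep(1, length(q)), i1 = rep(1, length(q)),
                                  w = rep(0, length(q))))
  i1 <- i0 + 1
  w <- (q - x[i0]) / (x[i1] - x[i0])
  w <- pmin(pmax(w, 0), 1)
  list(i0 = i0, i1 = i1, w = w)
}
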