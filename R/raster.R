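#' Planar single-band raster
#'
#' A minimal in-memory raster for planar (projected, metre-based) grids:
#' a numeric matrix plus an origin and square cell size. Row 1 of the matrix
#' is the southernmost row; column 1 the westernmost column, so
#' `values[iy, ix]` holds the cell whose centre is at
#' `(xmin + (ix - 0.5) * cell, ymin + (iy - 0.5) * cell)`.
#'
#' All package geometry is Euclidean in this planar frame; geographic
#' (lon/lat) inputs must be projected upstream.
#'
#' @param values Numeric matrix (rows = south-to-north, cols = west-to-east).
#' @param xmin,ymin Coordinates of the grid's south-west corner (metres).
#' @param cell_size Cell edge length in metres (> 0).
#' @param name Optional layer name.
#' @return An object of class `lur_raster`.
#' @export
#' @examples
#' r <- lur_raster(matrix(1:9, 3, 3), 0, 0, 100)
#' raster_value_at(r, 150, 150)
lur_raster <- function(values, xmin, ymin, cell_size, name = NULL) {
  stopifnot(is.matrix(values), is.numeric(cell_size), cell_size > 0)
  storage.mode(values) <- "double"
  structure(
    list(values = values, xmin = xmin, ymin = ymin, cell = cell_size,
         name = name),
    class = "lur_raster"
  )
}

#' @export
print.lur_raster <- function(x, ...) {
  e <- raster_extent(x)
  cat(sprintf("<lur_raster%s> %d x %d cells of %g m, extent x [%g, %g] y [%g, %g]\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              nrow(x$values), ncol(x$values), x$cell,
              e[["xmin"]], e[["xmax"]], e[["ymin"]], e[["ymax"]]))
  invisible(x)
}

#' @rdname lur_raster
#' @param x A `lur_raster`.
#' @export
raster_extent <- function(x) {
  c(xmin = x$xmin, xmax = x$xmin + ncol(x$values) * x$cell,
    ymin = x$ymin, ymax = x$ymin + nrow(x$values) * x$cell)
}

# Column/row index of the cell containing each point, half-open convention:
# a point on a cell boundary belongs to the cell whose interval
# [x0, x0 + cell) contains it. Points outside the extent give NA.
raster_cell_index <- function(raster, x, y) {
  ix <- floor((x - raster$xmin) / raster$cell) + 1
  iy <- floor((y - raster$ymin) / raster$cell) + 1
  ix[ix < 1 | ix > ncol(raster$values)] <- NA_integer_
  iy[iy < 1 | iy > nrow(raster$values)] <- NA_integer_
  list(ix = as.integer(ix), iy = as.integer(iy))
}

#' Raster value at point locations
#'
#' Nearest-cell (containing-cell) extraction with the half-open
#' `[x0, x0 + cell)` indexing convention: a site exactly on a cell boundary
#' takes the value of the cell starting at that boundary.
#'
#' @param raster A [lur_raster].
#' @param x,y Point coordinates (metres, planar).
#' @return Numeric vector of cell values; no-data cells give `NA`.
#'   Points outside the raster extent are an error.
#' @export
raster_value_at <- function(raster, x, y) {
  idx <- raster_cell_index(raster, x, y)
  if (anyNA(idx$ix) || anyNA(idx$iy)) {
    abort("raster_value_at(): point(s) outside the raster extent")
  }
  raster$values[cbind(idx$iy, idx$ix)]
}

#' @rdname lur_raster
#' @param ... Unused.
#' @export
as_tibble.lur_raster <- function(x, ...) {
  nx <- ncol(x$values); ny <- nrow(x$values)
  xs <- rep(x$xmin + (seq_len(nx) - 0.5) * x$cell, each = ny)
  ys <- rep(x$ymin + (seq_len(ny) - 0.5) * x$cell, times = nx)
  vs <- as.vector(x$values)
  tibble(x = xs, y = ys, value = vs)
}

#' Read/write a raster as Esri ASCII grid
#'
#' Plain-text raster exchange format (`ncols/nrows/xllcorner/yllcorner/`
#' `cellsize/NODATA_value` header followed by rows north to south).
#'
#' @param raster A [lur_raster].
#' @param path File path.
#' @param nodata Value used to encode `NA` on disk.
#' @return `write_ascii_grid()` returns `path` invisibly;
#'   `read_ascii_grid()` returns a [lur_raster].
#' @export
write_ascii_grid <- function(raster, path, nodata = -9999) {
  v <- raster$values
  v[is.na(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", raster$xmin),
    sprintf("yllcorner %.10g", raster$ymin),
    sprintf("cellsize %.10g", raster$cell),
    sprintf("NODATA_value %.10g", nodata)
  )
  rows <- apply(v[rev(seq_len(nrow(v))), , drop = FALSE], 1,
                function(r) paste(format(r, digits = 17, trim = TRUE),
                                  collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  kv <- setNames(vapply(hdr, function(h) as.numeric(h[2]), 0),
                 tolower(vapply(hdr, `[`, "", 1)))
  body <- lines[-(1:6)]
  vals <- lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, vals)
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  m[m == kv[["nodata_value"]]] <- NA_real_
  lur_raster(m, kv[["xllcorner"]], kv[["yllcorner"]], kv[["cellsize"]])
}

#' @export
autoplot.lur_raster <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = "x (m)", y = "y (m)",
                  fill = object$name %||% "value")
}
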