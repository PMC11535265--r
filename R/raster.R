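#' A planar single-band raster grid
#'
#' `raster_grid()` wraps a numeric matrix together with the planar grid
#' transform used throughout the package: `origin` is the (x, y) coordinate of
#' the *upper-left corner* of the grid, rows run top to bottom (y decreasing
#' with row index), columns left to right, and every cell is square with side
#' `cell_size` (metres). Missing cells are `NA` and are excluded from all
#' statistics.
#'
#' @param values Numeric matrix of cell values (row 1 = top row).
#' @param origin Length-2 numeric, (x, y) of the upper-left corner.
#' @param cell_size Cell side length in metres; must be positive.
#' @param name Optional layer name.
#'
#' @return An object of class `raster_grid`.
#' @export
#' @examples
#' r <- raster_grid(matrix(1:12, 3, 4), origin = c(0, 300), cell_size = 100)
#' raster_cell_centers(r)
raster_grid <- function(values, origin = c(0, nrow(values) * cell_size),
                        cell_size = 1, name = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(is.numeric(origin), length(origin) == 2L)
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    stop("`cell_size` must be a single positive number", call. = FALSE)
  }
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("raster must have positive dimensions", call. = FALSE)
  }
  structure(
    list(values = values, origin = as.numeric(origin),
         cell_size = as.numeric(cell_size), name = name),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf(
    "<raster_grid%s> %d x %d cells @ %g m, origin (%g, %g)\n",
    if (is.null(x$name)) "" else paste0(" ", x$name),
    nrow(x$values), ncol(x$values), x$cell_size, x$origin[1], x$origin[2]
  ))
  if (length(v)) {
    cat(sprintf("  values: [%g, %g], %d valid of %d cells\n",
                min(v), max(v), length(v), length(x$values)))
  } else {
    cat("  all cells NA\n")
  }
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' Cell-center coordinates of a raster grid
#'
#' @param r A [raster_grid()].
#' @return A tibble with one row per cell: `row`, `col`, `x`, `y`, `value`.
#' @export
raster_cell_centers <- function(r) {
  stopifnot(inherits(r, "raster_grid"))
  nr <- nrow(r$values); nc <- ncol(r$values)
  tibble::tibble(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    x = r$origin[1] + (rep(seq_len(nc), each = nr) - 0.5) * r$cell_size,
    y = r$origin[2] - (rep(seq_len(nr), times = nc) - 0.5) * r$cell_size,
    value = as.vector(r$values)
  )
}

#' @export
as_tibble.raster_grid <- function(x, ...) raster_cell_centers(x)

#' Locate the cell containing each point
#'
#' Points on the exact right/bottom edge of the extent are assigned to the
#' last column/row so that localities drawn inside the closed extent always
#' land in a cell.
#'
#' @param r A [raster_grid()].
#' @param x,y Point coordinates (same planar CRS as the grid).
#' @return A tibble with `row`, `col`, and the cell `value`; `NA` row/col for
#'   points outside the extent.
#' @export
raster_locate <- function(r, x, y) {
  stopifnot(inherits(r, "raster_grid"))
  nr <- nrow(r$values); nc <- ncol(r$values)
  col <- floor((x - r$origin[1]) / r$cell_size) + 1
  row <- floor((r$origin[2] - y) / r$cell_size) + 1
  col[x == r$origin[1] + nc * r$cell_size] <- nc
  row[y == r$origin[2] - nr * r$cell_size] <- nr
  bad <- row < 1 | row > nr | col < 1 | col > nc | is.na(x) | is.na(y)
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  val <- rep(NA_real_, length(x))
  ok <- !bad
  val[ok] <- r$values[cbind(row[ok], col[ok])]
  tibble::tibble(row = as.integer(row), col = as.integer(col), value = val)
}

#' Write / read a raster as an Arc/Info ASCII grid
#'
#' Plain-text raster interchange: a 6-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by one row
#' of numbers per grid row, top row first. `NA` cells are written as the
#' nodata value (-9999 by default).
#'
#' @param r A [raster_grid()].
#' @param path File path.
#' @param nodata Sentinel written for `NA` cells.
#' @return `write_ascii_grid()` returns `path` invisibly; `read_ascii_grid()`
#'   returns a [raster_grid()].
#' @export
write_ascii_grid <- function(r, path, nodata = -9999) {
  stopifnot(inherits(r, "raster_grid"))
  nr <- nrow(r$values); nc <- ncol(r$values)
  header <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", r$origin[1]),
    sprintf("yllcorner %.10g", r$origin[2] - nr * r$cell_size),
    sprintf("cellsize %.10g", r$cell_size),
    sprintf("NODATA_value %g", nodata)
  )
  v <- r$values
  v[is.na(v)] <- nodata
  rows <- apply(v, 1L, function(z) paste(format(z, trim = TRUE, digits = 10),
                                         collapse = " "))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[`, "", 1L))
  vals <- as.numeric(vapply(hdr, `[`, "", 2L))
  names(vals) <- keys
  nc <- as.integer(vals[["ncols"]]); nr <- as.integer(vals[["nrows"]])
  cs <- vals[["cellsize"]]
  nodata <- if ("nodata_value" %in% keys) vals[["nodata_value"]] else -9999
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  stopifnot(length(body) == nr * nc)
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  raster_grid(m, origin = c(vals[["xllcorner"]], vals[["yllcorner"]] + nr * cs),
              cell_size = cs)
}

#' Plot a raster grid
#'
#' @param object A [raster_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.raster_grid <- function(object, ...) {
  df <- raster_cell_centers(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = object$name %||% "value")
}
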