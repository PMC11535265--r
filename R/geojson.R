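#' Read and write point and polyline features as GeoJSON
#'
#' Vector features travel through the package in two simple forms: point
#' layers are tibbles with `x`, `y` and any attribute columns; polyline
#' layers are lists of coordinate matrices (one n-by-2 matrix of x, y vertices
#' per line). These helpers serialize either form as a GeoJSON
#' FeatureCollection so rivers, industries and localities interoperate with
#' standard GIS tools.
#'
#' @param points Tibble with `x`, `y` and optional attribute columns.
#' @param lines List of numeric matrices, each with columns x, y.
#' @param path File path.
#' @name geojson
NULL

#' @rdname geojson
#' @export
write_geojson_points <- function(points, path) {
  stopifnot(all(c("x", "y") %in% names(points)))
  attrs <- points[setdiff(names(points), c("x", "y"))]
  features <- purrr::map(seq_len(nrow(points)), function(i) {
    props <- if (ncol(attrs)) as.list(attrs[i, , drop = FALSE]) else
      stats::setNames(list(), character())
    list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(points$x[i], points$y[i])),
      properties = props
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname geojson
#' @export
write_geojson_lines <- function(lines, path) {
  features <- purrr::map(seq_along(lines), function(i) {
    m <- lines[[i]]
    list(
      type = "Feature",
      geometry = list(type = "LineString",
                      coordinates = lapply(seq_len(nrow(m)),
                                           function(j) as.numeric(m[j, 1:2]))),
      properties = list(id = i)
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname geojson
#' @export
read_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  stopifnot(identical(gj$type, "FeatureCollection"))
  types <- vapply(gj$features, function(f) f$geometry$type, "")
  if (all(types == "Point")) {
    coords <- t(vapply(gj$features,
                       function(f) as.numeric(unlist(f$geometry$coordinates)),
                       numeric(2)))
    props <- purrr::map(gj$features, function(f) {
      p <- f$properties
      if (is.null(p) || !length(p)) tibble::tibble(.rows = 1) else
        tibble::as_tibble(lapply(p, function(v) if (is.null(v)) NA else v))
    })
    out <- dplyr::bind_rows(props)
    out$x <- coords[, 1]; out$y <- coords[, 2]
    dplyr::relocate(out, "x", "y")
  } else if (all(types == "LineString")) {
    purrr::map(gj$features, function(f) {
      do.call(rbind, lapply(f$geometry$coordinates, as.numeric))
    })
  } else {
    stop("only homogeneous Point or LineString collections are supported",
         call. = FALSE)
  }
}
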