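#' Euclidean distance raster from vector features
#'
#' Fills every valid cell of `template` with the planar Euclidean distance
#' from its center to the nearest feature. Features are either a point layer
#' (tibble/data frame with `x`, `y`) or a polyline layer (list of n-by-2
#' vertex matrices); polyline distance is the exact point-to-segment distance,
#' minimized over all segments. The surface is continuous — distance buffers
#' shown on maps are a binned visualization of this raster, not the model
#' input.
#'
#' @param features Point tibble or list of line vertex matrices.
#' @param template A [raster_grid()] defining the output grid.
#' @return A [raster_grid()] of distances in metres; nodata cells of the
#'   template stay `NA`.
#' @export
distance_raster <- function(features, template) {
  stopifnot(inherits(template, "raster_grid"))
  segs <- as_segments(features)
  if (nrow(segs) == 0L) stop("empty feature set", call. = FALSE)
  cc <- raster_cell_centers(template)
  px <- cc$x; py <- cc$y
  d2 <- rep(Inf, length(px))
  for (i in seq_len(nrow(segs))) {
    ax <- segs[i, 1]; ay <- segs[i, 2]; bx <- segs[i, 3]; by <- segs[i, 4]
    dx <- bx - ax; dy <- by - ay
    len2 <- dx * dx + dy * dy
    if (len2 == 0) {
      qx <- ax; qy <- ay
    } else {
      t <- pmin(pmax(((px - ax) * dx + (py - ay) * dy) / len2, 0), 1)
      qx <- ax + t * dx; qy <- ay + t * dy
    }
    d2 <- pmin(d2, (px - qx)^2 + (py - qy)^2)
  }
  out <- template
  vals <- sqrt(d2)
  vals[is.na(as.vector(template$values))] <- NA_real_
  out$values <- matrix(vals, nrow(template$values), ncol(template$values))
  out$name <- "distance"
  out
}

# Normalize features to a segment table (ax, ay, bx, by); points degenerate.
as_segments <- function(features) {
  if (is.data.frame(features)) {
    stopifnot(all(c("x", "y") %in% names(features)))
    cbind(features$x, features$y, features$x, features$y)
  } else if (is.list(features)) {
    segs <- lapply(features, function(m) {
      m <- as.matrix(m)
      if (nrow(m) == 1L) return(cbind(m[1, 1], m[1, 2], m[1, 1], m[1, 2]))
      cbind(m[-nrow(m), 1], m[-nrow(m), 2], m[-1, 1], m[-1, 2])
    })
    if (!length(segs)) return(matrix(numeric(), 0L, 4L))
    do.call(rbind, segs)
  } else if (is.matrix(features)) {
    as_segments(list(features))
  } else {
    stop("features must be a point data frame or a list of line matrices",
         call. = FALSE)
  }
}

#' Bundle aligned rasters into a covariate stack
#'
#' All layers must share shape, origin, and cell size. The stack is the
#' spatial fabric the suitability model is fitted on.
#'
#' @param layers Named list of [raster_grid()] objects on one grid.
#' @return An object of class `covariate_stack` with elements `layers` and
#'   `grid` (the shared template).
#' @export
covariate_stack <- function(layers) {
  stopifnot(is.list(layers), length(layers) >= 1L,
            !is.null(names(layers)), all(nzchar(names(layers))))
  ref <- layers[[1]]
  for (nm in names(layers)) {
    l <- layers[[nm]]
    stopifnot(inherits(l, "raster_grid"))
    if (!identical(dim(l$values), dim(ref$values)) ||
        !isTRUE(all.equal(l$origin, ref$origin)) ||
        !isTRUE(all.equal(l$cell_size, ref$cell_size))) {
      stop("layer '", nm, "' is not on the shared grid", call. = FALSE)
    }
    layers[[nm]]$name <- nm
  }
  template <- ref
  template$values <- matrix(0, nrow(ref$values), ncol(ref$values))
  template$name <- NULL
  structure(list(layers = layers, grid = template), class = "covariate_stack")
}

#' @export
print.covariate_stack <- function(x, ...) {
  cat(sprintf("<covariate_stack> %d layers on a %d x %d grid @ %g m\n",
              length(x$layers), nrow(x$grid$values), ncol(x$grid$values),
              x$grid$cell_size))
  cat(" ", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' Stack values as a tibble
#'
#' One row per cell with a column per layer; `valid` flags cells with no
#' missing layer.
#'
#' @param x A [covariate_stack()].
#' @param ... Unused.
#' @return A tibble.
#' @export
as_tibble.covariate_stack <- function(x, ...) {
  out <- raster_cell_centers(x$grid)[c("row", "col", "x", "y")]
  for (nm in names(x$layers)) out[[nm]] <- as.vector(x$layers[[nm]]$values)
  out$valid <- stats::complete.cases(out[names(x$layers)])
  out
}

# Bilinear sample of raster `src` at points (x, y); NA outside the hull of
# cell centers or when any contributing cell is NA.
bilinear_sample <- function(src, x, y) {
  nr <- nrow(src$values); nc <- ncol(src$values)
  # fractional cell-center coordinates
  fc <- (x - src$origin[1]) / src$cell_size + 0.5
  fr <- (src$origin[2] - y) / src$cell_size + 0.5
  c0 <- floor(fc); r0 <- floor(fr)
  wc <- fc - c0; wr <- fr - r0
  # clamp to the edge so points between the border center and the edge use
  # the nearest cells
  c0c <- pmin(pmax(c0, 1), nc - 1); r0c <- pmin(pmax(r0, 1), nr - 1)
  wc <- pmin(pmax(wc + (c0 - c0c), 0), 1)
  wr <- pmin(pmax(wr + (r0 - r0c), 0), 1)
  inside <- x >= src$origin[1] & x <= src$origin[1] + nc * src$cell_size &
    y <= src$origin[2] & y >= src$origin[2] - nr * src$cell_size
  v00 <- src$values[cbind(r0c, c0c)]
  v01 <- src$values[cbind(r0c, c0c + 1)]
  v10 <- src$values[cbind(r0c + 1, c0c)]
  v11 <- src$values[cbind(r0c + 1, c0c + 1)]
  out <- (1 - wr) * ((1 - wc) * v00 + wc * v01) +
    wr * ((1 - wc) * v10 + wc * v11)
  out[!inside] <- NA_real_
  out
}

#' Align layers onto a target grid
#'
#' Continuous layers are resampled bilinearly to the target cell centers.
#' Distance layers should not be resampled but recomputed: pass their source
#' vectors in `vectors` (named to match the layer) and the distance surface is
#' rebuilt exactly on the target grid. Nodata propagates as the union of
#' missingness across contributing cells.
#'
#' @param layers Named list of [raster_grid()] objects (arbitrary grids).
#' @param target A [raster_grid()] defining the analysis grid.
#' @param vectors Optional named list of feature layers for exact
#'   recomputation of distance rasters.
#' @return A [covariate_stack()] on the target grid.
#' @export
align_stack <- function(layers, target, vectors = list()) {
  stopifnot(inherits(target, "raster_grid"))
  cc <- raster_cell_centers(target)
  aligned <- lapply(names(layers), function(nm) {
    if (nm %in% names(vectors)) {
      return(distance_raster(vectors[[nm]], target))
    }
    src <- layers[[nm]]
    same_grid <- identical(dim(src$values), dim(target$values)) &&
      isTRUE(all.equal(src$origin, target$origin)) &&
      isTRUE(all.equal(src$cell_size, target$cell_size))
    out <- target
    if (same_grid) {
      out$values <- src$values
    } else {
      vals <- bilinear_sample(src, cc$x, cc$y)
      if (all(is.na(vals))) {
        stop("layer '", nm, "' does not overlap the target grid",
             call. = FALSE)
      }
      out$values <- matrix(vals, nrow(target$values), ncol(target$values))
    }
    out$name <- nm
    out
  })
  names(aligned) <- names(layers)
  covariate_stack(aligned)
}

#' Pairwise Pearson correlation of stack layers
#'
#' Computed over mutually valid cells (cells with no missing value in any
#' layer).
#'
#' @param stack A [covariate_stack()].
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
stack_correlation <- function(stack) {
  df <- as_tibble(stack)
  m <- as.matrix(df[df$valid, names(stack$layers), drop = FALSE])
  if (nrow(m) < 3L) stop("need at least 3 mutually valid cells", call. = FALSE)
  suppressWarnings(cor(m))
}

#' Screen collinear covariates
#'
#' Implements the |r| < `threshold` independence rule: while any layer pair
#' has |Pearson r| at or above the threshold, the member of the worst
#' offending pair with the larger mean absolute correlation against all other
#' retained layers is dropped. Zero-variance layers have undefined r and are
#' dropped first with a warning. The screen is deterministic and idempotent.
#'
#' @param stack A [covariate_stack()].
#' @param threshold Absolute-correlation threshold (default 0.85).
#' @return A list: `stack` (retained layers), `retained`, `dropped` (tibble
#'   log with reasons), `correlation` (full input matrix).
#' @export
collinearity_screen <- function(stack, threshold = 0.85) {
  stopifnot(inherits(stack, "covariate_stack"), length(stack$layers) >= 2L)
  df <- as_tibble(stack)
  m <- as.matrix(df[df$valid, names(stack$layers), drop = FALSE])
  if (nrow(m) < 3L) stop("need at least 3 mutually valid cells", call. = FALSE)

  drop_log <- tibble::tibble(layer = character(), reason = character())
  keep <- colnames(m)
  sds <- apply(m, 2, sd)
  flat <- keep[sds == 0 | !is.finite(sds)]
  if (length(flat)) {
    warning("dropping zero-variance layer(s): ", paste(flat, collapse = ", "),
            call. = FALSE)
    drop_log <- dplyr::bind_rows(drop_log, tibble::tibble(
      layer = flat, reason = "zero variance (r undefined)"))
    keep <- setdiff(keep, flat)
  }
  full_r <- suppressWarnings(cor(m))

  while (length(keep) >= 2L) {
    r <- cor(m[, keep, drop = FALSE])
    ar <- abs(r); diag(ar) <- 0
    worst <- max(ar)
    if (worst < threshold) break
    idx <- which(ar == worst, arr.ind = TRUE)[1, ]
    pair <- keep[c(idx[["row"]], idx[["col"]])]
    mean_ar <- colSums(ar[, pair, drop = FALSE]) / (length(keep) - 1L)
    # drop the pair member with the larger mean |r|; ties break on the later
    # layer name so the outcome is deterministic
    victim <- if (mean_ar[1] > mean_ar[2]) pair[1]
      else if (mean_ar[2] > mean_ar[1]) pair[2]
      else sort(pair)[2]
    drop_log <- dplyr::bind_rows(drop_log, tibble::tibble(
      layer = victim,
      reason = sprintf("|r| = %.3f with %s (threshold %.2f)", worst,
                       setdiff(pair, victim), threshold)))
    keep <- setdiff(keep, victim)
  }

  list(
    stack = covariate_stack(stack$layers[keep]),
    retained = keep,
    dropped = drop_log,
    correlation = full_r
  )
}
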