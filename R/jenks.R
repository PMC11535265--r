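#' Fisher-Jenks natural breaks
#'
#' Finds the contiguous partition of the sorted values into `k` classes that
#' minimizes the total within-class sum of squared deviations (equivalently,
#' maximizes between-class variance), by exact dynamic programming. Among
#' cost-optimal partitions the one with the lexicographically smallest breaks
#' is returned, so the result is deterministic.
#'
#' For rasters larger than `subsample` valid cells, the optimum is computed
#' exactly on a seeded uniform subsample of the values (the partition is
#' still the exact optimum for that sample).
#'
#' Break values: element 1 is the data minimum, element `k + 1` the data
#' maximum, and each internal break is the smallest value of the next class
#' up, so classification with half-open intervals reproduces the optimal
#' partition exactly.
#'
#' @param values Numeric vector (NAs dropped).
#' @param k Number of classes; needs at least `k` distinct values.
#' @param subsample Maximum number of values the exact DP runs on.
#' @param seed Seed used only when subsampling.
#' @return An object of class `jenks_breaks`: `k`, `breaks` (length
#'   `k + 1`), `ssd` (total within-class SSD), `classes` (per-class bounds,
#'   counts and means on the fitted sample), `n` (sample size used).
#' @export
#' @examples
#' fisher_jenks(c(1, 2, 10, 11, 20, 21), k = 3)
fisher_jenks <- function(values, k, subsample = 20000L, seed = 1L) {
  v <- values[!is.na(values)]
  if (k < 1L) stop("k must be at least 1", call. = FALSE)
  if (length(unique(v)) < k) {
    stop("need at least k distinct values", call. = FALSE)
  }
  if (length(v) > subsample) {
    set.seed(sub_seed(seed, "zones"))
    v <- sample(v, subsample)
  }
  x <- sort(v)
  res <- jenks_dp(x, as.integer(k))
  ends <- res$ends
  starts <- c(1L, head(ends, -1L) + 1L)
  breaks <- c(x[1], x[starts[-1L]], x[length(x)])
  if (k == 1L) breaks <- c(x[1], x[length(x)])
  classes <- tibble::tibble(
    zone = seq_len(k),
    lower = x[starts],
    upper = x[ends],
    n = ends - starts + 1L,
    mean = vapply(seq_len(k), function(i) {
      mean(x[starts[i]:ends[i]])
    }, numeric(1))
  )
  structure(list(k = as.integer(k), breaks = breaks, ssd = res$ssd,
                 classes = classes, n = length(x)),
            class = "jenks_breaks")
}

#' @export
print.jenks_breaks <- function(x, ...) {
  cat(sprintf("<jenks_breaks> k = %d, SSD = %.6g (n = %d)\n",
              x$k, x$ssd, x$n))
  cat("  breaks:", paste(format(x$breaks, digits = 4), collapse = " | "),
      "\n")
  invisible(x)
}

#' @export
tidy.jenks_breaks <- function(x, ...) x$classes

#' Classify a suitability surface into exposure zones
#'
#' Labels every valid cell with its class under the break set: class `c`
#' covers the half-open interval `[breaks[c], breaks[c + 1])`, the top class
#' is closed above, and a value exactly equal to an internal break goes to
#' the higher class. Values outside the break range are clamped into the
#' nearest class and counted in the `clamped` attribute (with a warning).
#' Labels are monotone in suitability: 1 = lowest exposure.
#'
#' @param suitability A [raster_grid()], a [logistic_map()] result (its
#'   logistic layer is used), or a numeric vector.
#' @param breaks A [fisher_jenks()] object (its full break vector is used),
#'   or a numeric vector of `k - 1` internal cut points, in which case the
#'   data range bounds the outer classes.
#' @return For raster input, a `zone_map` (label raster plus the breaks
#'   used); for vector input, an integer vector of labels.
#' @export
classify_zones <- function(suitability, breaks) {
  if (inherits(suitability, "suitability_map")) {
    suitability <- suitability$logistic
  }
  vals <- if (inherits(suitability, "raster_grid")) {
    as.vector(suitability$values)
  } else {
    as.numeric(suitability)
  }
  if (inherits(breaks, "jenks_breaks")) {
    brk <- breaks$breaks
  } else {
    # numeric input is the internal cut points; the data range bounds the
    # outer classes
    rng <- range(vals, na.rm = TRUE)
    brk <- c(rng[1], as.numeric(breaks), rng[2])
  }
  if (is.unsorted(brk, strictly = TRUE)) {
    stop("breaks must be strictly ascending", call. = FALSE)
  }
  k <- length(brk) - 1L
  ok <- !is.na(vals)
  n_clamp <- sum(vals[ok] < brk[1] | vals[ok] > brk[k + 1L])
  if (n_clamp > 0L) {
    warning(n_clamp, " value(s) outside the break range were clamped",
            call. = FALSE)
  }
  clamped <- pmin(pmax(vals, brk[1]), brk[k + 1L])
  lab <- findInterval(clamped, brk, rightmost.closed = TRUE)
  lab[!ok] <- NA_integer_

  if (inherits(suitability, "raster_grid")) {
    r <- suitability
    r$values <- matrix(as.numeric(lab), nrow(r$values), ncol(r$values))
    r$name <- "zone"
    structure(list(raster = r, breaks = brk, k = k, clamped = n_clamp),
              class = "zone_map")
  } else {
    attr(lab, "clamped") <- n_clamp
    as.integer(lab)
  }
}

#' @export
print.zone_map <- function(x, ...) {
  tab <- table(factor(x$raster$values, levels = seq_len(x$k)))
  cat(sprintf("<zone_map> %d zones over %d labeled cells\n", x$k,
              sum(tab)))
  cat("  breaks:", paste(format(x$breaks, digits = 4), collapse = " | "),
      "\n")
  cat("  cells per zone:", paste(as.integer(tab), collapse = " / "), "\n")
  invisible(x)
}

#' @export
autoplot.zone_map <- function(object, ...) {
  df <- raster_cell_centers(object$raster)
  labels <- if (object$k == 3L) {
    c("low", "medium", "very high")
  } else {
    paste("zone", seq_len(object$k))
  }
  df$zone <- factor(df$value, levels = seq_len(object$k), labels = labels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$zone)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_brewer(palette = "YlOrRd", na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "exposure")
}

#' Quantile breaks (for comparison in tests only)
#'
#' @param values Numeric vector.
#' @param k Number of classes.
#' @return A numeric break vector of length `k + 1`.
#' @keywords internal
#' @export
quantile_breaks <- function(values, k) {
  v <- values[!is.na(values)]
  as.numeric(stats::quantile(v, probs = seq(0, 1, length.out = k + 1),
                             names = FALSE))
}
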