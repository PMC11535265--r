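# Independent oracles used across the suite. These deliberately use naive
# scalar algorithms (enumeration, per-cell loops) so they share no code with
# the implementation paths they check.

# Exhaustive Fisher-Jenks: enumerate every contiguous partition of the sorted
# values into k classes and return the minimal total within-class SSD with
# the lexicographically smallest boundary positions.
brute_jenks <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  ssd <- function(v) sum((v - mean(v))^2)
  if (k == 1L) {
    return(list(ssd = ssd(x), ends = n))
  }
  cuts <- utils::combn(n - 1L, k - 1L)
  best <- Inf
  best_ends <- NULL
  for (i in seq_len(ncol(cuts))) {
    ends <- c(cuts[, i], n)
    starts <- c(1L, head(ends, -1L) + 1L)
    tot <- sum(vapply(seq_len(k),
                      function(c) ssd(x[starts[c]:ends[c]]), numeric(1)))
    if (tot < best - 1e-12) {
      best <- tot
      best_ends <- ends
    }
  }
  list(ssd = best, ends = best_ends)
}

# Per-cell scalar scan: distance from every cell center to the nearest
# feature (points or polylines), minimizing over features one cell at a time.
brute_distance <- function(features, template) {
  segs <- if (is.data.frame(features)) {
    lapply(seq_len(nrow(features)), function(i) {
      c(features$x[i], features$y[i], features$x[i], features$y[i])
    })
  } else {
    out <- list()
    for (m in features) {
      m <- as.matrix(m)
      if (nrow(m) == 1L) {
        out[[length(out) + 1L]] <- c(m[1, 1], m[1, 2], m[1, 1], m[1, 2])
      } else {
        for (j in seq_len(nrow(m) - 1L)) {
          out[[length(out) + 1L]] <- c(m[j, 1], m[j, 2], m[j + 1, 1],
                                       m[j + 1, 2])
        }
      }
    }
    out
  }
  pt_seg <- function(px, py, s) {
    dx <- s[3] - s[1]; dy <- s[4] - s[2]
    l2 <- dx * dx + dy * dy
    if (l2 == 0) return(sqrt((px - s[1])^2 + (py - s[2])^2))
    t <- ((px - s[1]) * dx + (py - s[2]) * dy) / l2
    t <- min(max(t, 0), 1)
    sqrt((px - (s[1] + t * dx))^2 + (py - (s[2] + t * dy))^2)
  }
  out <- template
  nr <- nrow(template$values); nc <- ncol(template$values)
  for (r in seq_len(nr)) {
    for (cl in seq_len(nc)) {
      px <- template$origin[1] + (cl - 0.5) * template$cell_size
      py <- template$origin[2] - (r - 0.5) * template$cell_size
      out$values[r, cl] <- min(vapply(segs, function(s) pt_seg(px, py, s),
                                      numeric(1)))
    }
  }
  out
}

# AUC by explicit pair counting, ties worth one half.
brute_auc <- function(p, b) {
  wins <- 0
  for (i in seq_along(p)) {
    for (j in seq_along(b)) {
      wins <- wins + (p[i] > b[j]) + 0.5 * (p[i] == b[j])
    }
  }
  wins / (length(p) * length(b))
}

# A tiny covariate stack from plain matrices (shared 1-unit grid helper).
make_stack <- function(..., cell_size = 100) {
  mats <- list(...)
  layers <- lapply(names(mats), function(nm) {
    raster_grid(mats[[nm]], origin = c(0, nrow(mats[[nm]]) * cell_size),
                cell_size = cell_size, name = nm)
  })
  names(layers) <- names(mats)
  covariate_stack(layers)
}
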