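tpl <- function(nr = 20, nc = 20, cs = 100) {
  raster_grid(matrix(0, nr, nc), origin = c(0, nr * cs), cell_size = cs)
}

test_that("a point at a cell center gives zero there; lines give k*cell", {
  t <- tpl(10, 10)
  d <- distance_raster(tibble::tibble(x = 350, y = 650), t)
  expect_equal(d$values[4, 4], 0)          # (row 4, col 4) center = (350, 650)
  # vertical line through the column-3 centers
  line <- list(cbind(c(250, 250), c(0, 1000)))
  dl <- distance_raster(line, t)
  for (k in 0:6) {
    expect_equal(dl$values[5, 3 + k], k * 100, tolerance = 1e-9)
  }
  expect_error(distance_raster(list(), t), "empty")
})

test_that("distance_raster equals the brute-force per-cell scan", {
  set.seed(404)
  t <- tpl(20, 20)
  pts <- tibble::tibble(x = runif(3, 0, 2000), y = runif(3, 0, 2000))
  expect_equal(distance_raster(pts, t)$values,
               brute_distance(pts, t)$values, tolerance = 1e-12)
  lines <- list(cbind(runif(4, 0, 2000), runif(4, 0, 2000)),
                cbind(runif(3, 0, 2000), runif(3, 0, 2000)))
  expect_equal(distance_raster(lines, t)$values,
               brute_distance(lines, t)$values, tolerance = 1e-12)
})

test_that("alignment is the identity on the target grid", {
  t <- tpl(8, 8)
  src <- t
  src$values <- matrix(rnorm(64), 8, 8)
  st <- align_stack(list(a = src), t)
  expect_identical(st$layers$a$values, src$values)
})

test_that("constant layers stay constant across resolutions", {
  fine <- raster_grid(matrix(3.5, 40, 40), origin = c(0, 2000),
                      cell_size = 50)
  coarse <- tpl(10, 10, 200)
  st <- align_stack(list(c = fine), coarse)
  expect_true(all(abs(st$layers$c$values - 3.5) < 1e-12))
})

test_that("bilinear 2x coarsening of a linear ramp is exact", {
  # values are a ramp in x evaluated at the fine cell centers
  nr <- 20; nc <- 20
  fine <- raster_grid(matrix(0, nr, nc), origin = c(0, 1000), cell_size = 50)
  cc <- raster_cell_centers(fine)
  fine$values <- matrix(2 * cc$x + 7, nr, nc)
  coarse <- tpl(10, 10, 100)
  st <- align_stack(list(ramp = fine), coarse)
  cc2 <- raster_cell_centers(coarse)
  expect_equal(as.vector(st$layers$ramp$values),
               2 * cc2$x + 7, tolerance = 1e-9)
})

test_that("disjoint extents are rejected", {
  far <- raster_grid(matrix(1, 5, 5), origin = c(1e6, 1e6 + 500),
                     cell_size = 100)
  expect_error(align_stack(list(far = far), tpl(5, 5)), "overlap")
})

test_that("distance layers are recomputed, not resampled, when vectors given", {
  pts <- tibble::tibble(x = 120, y = 480)
  fine <- distance_raster(pts, tpl(40, 40, 25))
  coarse_tpl <- tpl(10, 10, 100)
  st <- align_stack(list(dist = fine), coarse_tpl,
                    vectors = list(dist = pts))
  expect_equal(st$layers$dist$values,
               distance_raster(pts, coarse_tpl)$values)
})

test_that("stack correlation matches the textbook Pearson formula", {
  set.seed(11)
  a <- matrix(rnorm(25), 5, 5)
  b <- matrix(rnorm(25), 5, 5)
  st <- make_stack(a = a, b = b)
  r <- stack_correlation(st)
  va <- as.vector(a); vb <- as.vector(b)
  manual <- sum((va - mean(va)) * (vb - mean(vb))) /
    sqrt(sum((va - mean(va))^2) * sum((vb - mean(vb))^2))
  expect_equal(r["a", "b"], manual, tolerance = 1e-12)
  expect_equal(r, t(r))
  expect_equal(diag(r), c(a = 1, b = 1))
})

test_that("duplicate layers are screened out; independents are kept", {
  set.seed(2)
  a <- matrix(rnorm(400), 20, 20)
  c_ <- matrix(rnorm(400), 20, 20)
  scr <- collinearity_screen(make_stack(A = a, B = a, C = c_))
  expect_length(scr$retained, 2)
  expect_true("C" %in% scr$retained)
  expect_true(any(c("A", "B") %in% scr$retained))
  expect_equal(nrow(scr$dropped), 1L)

  # two independent white-noise layers stay below the threshold
  scr2 <- collinearity_screen(make_stack(A = a, C = c_))
  expect_setequal(scr2$retained, c("A", "C"))
})

test_that("the collinearity screen is idempotent", {
  set.seed(31)
  a <- matrix(rnorm(100), 10, 10)
  st <- make_stack(A = a, B = a + matrix(rnorm(100, sd = 0.01), 10, 10),
                   C = matrix(rnorm(100), 10, 10))
  scr <- collinearity_screen(st)
  scr2 <- collinearity_screen(scr$stack)
  expect_equal(scr2$retained, scr$retained)
  expect_equal(nrow(scr2$dropped), 0L)
})

test_that("zero-variance layers are flagged and dropped", {
  set.seed(5)
  st <- make_stack(flat = matrix(1, 10, 10),
                   A = matrix(rnorm(100), 10, 10),
                   B = matrix(rnorm(100), 10, 10))
  expect_warning(scr <- collinearity_screen(st), "zero-variance")
  expect_setequal(scr$retained, c("A", "B"))
  expect_true("flat" %in% scr$dropped$layer)
})

test_that("ascii grid round-trips values, grid transform and nodata", {
  r <- raster_grid(matrix(c(1.5, NA, 3, 4, 5, 6), 2, 3),
                   origin = c(100, 700), cell_size = 50)
  p <- tempfile(fileext = ".asc")
  write_ascii_grid(r, p)
  r2 <- read_ascii_grid(p)
  expect_equal(r2$values, r$values)
  expect_equal(r2$origin, r$origin)
  expect_equal(r2$cell_size, r$cell_size)
})

test_that("geojson round-trips points and lines", {
  pts <- tibble::tibble(id = c("a", "b"), x = c(1.5, 2.5), y = c(3, 4),
                        population = c(10, 20))
  p <- tempfile(fileext = ".geojson")
  write_geojson_points(pts, p)
  back <- read_geojson(p)
  expect_equal(back$x, pts$x)
  expect_equal(back$population, pts$population)
  lines <- list(cbind(c(0, 1, 2), c(0, 1, 0)), cbind(c(5, 6), c(5, 6)))
  pl <- tempfile(fileext = ".geojson")
  write_geojson_lines(lines, pl)
  back_l <- read_geojson(pl)
  expect_equal(back_l[[1]], unname(lines[[1]]))
  expect_equal(back_l[[2]], unname(lines[[2]]))
})
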