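# A small hand-assignable zone map: 3 vertical bands of a 6x6 grid,
# 200 m cells.
band_zones <- function() {
  m <- matrix(rep(1:3, each = 12), 6, 6)
  r <- raster_grid(m, origin = c(0, 1200), cell_size = 200)
  structure(list(raster = r, breaks = c(0, 1, 2, 3), k = 3L, clamped = 0L),
            class = "zone_map")
}

band_localities <- function() {
  tibble::tibble(
    locality_id = sprintf("L%d", 1:6),
    x = c(100, 300, 500, 700, 900, 1100),   # bands: 1,1,2,2,3,3
    y = rep(600, 6),
    population = c(1000, 2000, 1500, 500, 800, 1200),
    cases = c(1L, 2L, 3L, 1L, 8L, 9L)
  )
}

test_that("zonal summaries tally cases, population, area and rates", {
  zs <- zonal_summary(band_zones(), band_localities())
  expect_equal(zs$zone, 1:3)
  expect_equal(zs$cases, c(3L, 4L, 17L))
  expect_equal(zs$population, c(3000, 2000, 2000))
  expect_equal(zs$rate, 1e5 * zs$cases / zs$population)
  expect_equal(zs$area_km2, rep(12 * 0.04, 3))
  expect_equal(zs$n_localities, c(2L, 2L, 2L))
  # conservation
  expect_equal(sum(zs$cases), sum(band_localities()$cases))
  expect_equal(sum(zs$population), sum(band_localities()$population))
})

test_that("localities on nodata cells are rejected by id", {
  zm <- band_zones()
  zm$raster$values[3, 1] <- NA
  loc <- band_localities()
  loc$x[1] <- 100; loc$y[1] <- 1200 - 2.5 * 200   # cell (3, 1)
  expect_error(zonal_summary(zm, loc), "L1")
})

test_that("cases can be tallied from a mortality table", {
  mort <- tibble::tibble(locality_id = c("L1", "L1", "L5"),
                         deaths = c(2L, 1L, 4L))
  loc <- band_localities()[, c("locality_id", "x", "y", "population")]
  zs <- zonal_summary(band_zones(), loc, mortality = mort)
  expect_equal(zs$cases, c(3L, 0L, 4L))
})

test_that("2x2 tables partition cases and noncases by contrast", {
  zs <- zonal_summary(band_zones(), band_localities())
  t <- contingency_2x2(zs, exposed = 3, unexposed = c(1, 2))
  expect_equal(t$A, 17); expect_equal(t$B, 7)
  expect_equal(t$C, 2000 - 17); expect_equal(t$D, 5000 - 7)
  expect_equal(t$A + t$B + t$C + t$D, 7000)
  expect_error(contingency_2x2(zs, exposed = c(1, 3), unexposed = 1),
               "overlap")
  expect_error(contingency_2x2(zs, exposed = integer(), unexposed = 1),
               "non-empty")
})

fake_table <- function(A, B, C, D) {
  structure(list(A = A, B = B, C = C, D = D, contrast = "test"),
            class = "contingency_2x2")
}

test_that("odds ratios follow the cross-product rule", {
  expect_equal(as.numeric(odds_ratio(fake_table(10, 5, 100, 200))), 4)
  expect_equal(as.numeric(odds_ratio(fake_table(7, 7, 30, 30))), 1)
  # invariant to scaling every cell
  or1 <- as.numeric(odds_ratio(fake_table(13, 5, 120, 260)))
  or13 <- as.numeric(odds_ratio(fake_table(13 * 13, 5 * 13, 120 * 13,
                                           260 * 13)))
  expect_equal(or1, or13)
})

test_that("zero cells refuse by default and accept the Haldane correction", {
  t0 <- fake_table(5, 0, 100, 200)
  expect_error(odds_ratio(t0), "haldane")
  or <- odds_ratio(t0, haldane = TRUE)
  expect_true(attr(or, "haldane"))
  expect_equal(as.numeric(or), (5.5 * 200.5) / (0.5 * 100.5))
})

test_that("Woolf intervals match hand computation and log symmetry", {
  t <- fake_table(10, 5, 100, 200)
  ci <- odds_ratio_ci(t, method = "woolf")
  se <- sqrt(1 / 10 + 1 / 5 + 1 / 100 + 1 / 200)
  expect_equal(ci$lower, exp(log(4) - qnorm(0.975) * se), tolerance = 1e-12)
  expect_equal(ci$upper, exp(log(4) + qnorm(0.975) * se), tolerance = 1e-12)
  expect_equal(ci$lower, 1.3314, tolerance = 1e-3)
  expect_equal(ci$upper, 12.017, tolerance = 1e-3)
  expect_equal(sqrt(ci$lower * ci$upper), ci$or, tolerance = 1e-9)
  # degenerate level collapses onto the estimate
  ci1 <- odds_ratio_ci(t, alpha = 1)
  expect_equal(ci1$lower, ci1$or)
  expect_equal(ci1$upper, ci1$or)
})

test_that("the linear interval is arithmetically symmetric about the OR", {
  t <- fake_table(10, 5, 100, 200)
  ci <- odds_ratio_ci(t, method = "linear")
  expect_equal((ci$lower + ci$upper) / 2, ci$or, tolerance = 1e-12)
})

test_that("attributable fractions reproduce the published arithmetic", {
  expect_equal(round(as.numeric(attributable_fraction(3.37)), 1), 70.3)
  expect_equal(round(as.numeric(attributable_fraction(4.79)), 1), 79.1)
  expect_equal(round(as.numeric(attributable_fraction(9.22))), 89)
  expect_equal(round(as.numeric(attributable_fraction(5.35))), 81)
  expect_equal(round(as.numeric(attributable_fraction(4.03))), 75)
  expect_equal(as.numeric(attributable_fraction(1)), 0)
  prot <- attributable_fraction(0.8)
  expect_equal(as.numeric(prot), 0)
  expect_true(attr(prot, "protective"))
})

test_that("AF is monotone in OR and bounded in [0, 100)", {
  ors <- c(1, 1.5, 2, 4, 10, 100, 1e6)
  afs <- as.numeric(attributable_fraction(ors))
  expect_true(all(diff(afs) > 0))
  expect_true(all(afs >= 0 & afs < 100))
})

test_that("relative risk is the zone rate ratio", {
  # zone rates as published: 72.43 vs 28.99 per 100,000
  zs <- tibble::tibble(zone = c(2, 3), cases = c(28.99, 72.43),
                       population = c(1e5, 1e5))
  expect_equal(relative_risk(zs, exposed = 3, unexposed = 2),
               72.43 / 28.99, tolerance = 1e-12)
  expect_equal(round(relative_risk(zs, 3, 2), 3), 2.498)
  # equal rates
  zs2 <- tibble::tibble(zone = 1:2, cases = c(5, 10),
                        population = c(1e4, 2e4))
  expect_equal(relative_risk(zs2, 2, 1), 1)
  expect_error(relative_risk(tibble::tibble(zone = 1:2, cases = c(0, 3),
                                            population = c(100, 100)),
                             2, 1), "undefined")
})

test_that("the odds ratio is farther from the null than the risk ratio", {
  set.seed(42)
  for (i in 1:30) {
    A <- sample(1:50, 1); B <- sample(1:50, 1)
    C <- sample(100:5000, 1); D <- sample(100:5000, 1)
    zs <- tibble::tibble(zone = 1:2, cases = c(B, A),
                         population = c(B + D, A + C))
    or <- as.numeric(odds_ratio(fake_table(A, B, C, D)))
    rr <- relative_risk(zs, exposed = 2, unexposed = 1)
    if (rr >= 1) {
      expect_gte(or + 1e-12, rr)
    } else {
      expect_lte(or - 1e-12, rr)
    }
  }
})

test_that("zone_association bundles OR, CI, RR and AF coherently", {
  zs <- zonal_summary(band_zones(), band_localities())
  a <- zone_association(zs, exposed = 3, unexposed = c(1, 2))
  expect_s3_class(a, "association_result")
  expect_equal(a$or, as.numeric(odds_ratio(contingency_2x2(zs, 3, c(1, 2)))))
  expect_equal(a$af_percent,
               as.numeric(attributable_fraction(a$or)))
  td <- tidy(a)
  expect_equal(td$or, a$or)
  expect_equal(td$contrast, "zone 3 vs zone 1+2")
})
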