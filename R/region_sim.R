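#' Configuration for a synthetic study region
#'
#' Defines a small industrialized valley on a square grid: a smooth elevation
#' field, rivers crossing the region, point industries, a fine-particulate
#' (PM2.5) surface that decays exponentially with distance from industry, and
#' populated localities. Defaults describe a region of roughly 16 x 16 km at
#' 250 m resolution with PM2.5 well above 20 ug/m3 near the pollution sources
#' and a clean-air background, mirroring a heavily industrialized basin.
#'
#' @param grid_rows,grid_cols Grid dimensions (>= 8).
#' @param cell_size Cell side in metres.
#' @param n_rivers,n_industries Feature counts (>= 1).
#' @param n_localities Number of populated places (>= 3).
#' @param pm_background Background PM2.5 concentration (ug/m3).
#' @param pm_industry_amplitude Added PM2.5 at zero distance from an industry
#'   (ug/m3).
#' @param pm_decay_length e-folding distance of the industrial PM2.5 plume (m).
#' @param pm_noise_sd Standard deviation of cell-level Gaussian noise on the
#'   PM2.5 surface (ug/m3).
#' @param elevation_range Min/max elevation (m) the smooth field is rescaled to.
#' @param pop_range Locality populations are drawn log-uniformly in this range.
#' @param cause_code ICD-10 code attached to simulated deaths.
#' @param seed Integer seed; fans out to independent per-component substreams
#'   so adding one component never perturbs another.
#'
#' @return A list of class `region_config`.
#' @export
region_config <- function(grid_rows = 64, grid_cols = 64, cell_size = 250,
                          n_rivers = 2, n_industries = 5, n_localities = 60,
                          pm_background = 8, pm_industry_amplitude = 18,
                          pm_decay_length = 1500, pm_noise_sd = 0.5,
                          elevation_range = c(1700, 2100),
                          pop_range = c(500, 5000),
                          cause_code = "I259", seed = 1L) {
  cfg <- list(
    grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
    cell_size = cell_size, n_rivers = as.integer(n_rivers),
    n_industries = as.integer(n_industries),
    n_localities = as.integer(n_localities),
    pm_background = pm_background,
    pm_industry_amplitude = pm_industry_amplitude,
    pm_decay_length = pm_decay_length, pm_noise_sd = pm_noise_sd,
    elevation_range = elevation_range, pop_range = pop_range,
    cause_code = cause_code, seed = as.integer(seed)
  )
  if (cfg$grid_rows < 8L || cfg$grid_cols < 8L) {
    stop("grid must be at least 8 x 8", call. = FALSE)
  }
  if (cfg$cell_size <= 0) stop("cell_size must be positive", call. = FALSE)
  if (cfg$n_localities < 3L) stop("need at least 3 localities", call. = FALSE)
  if (cfg$n_rivers < 1L || cfg$n_industries < 1L) {
    stop("river and industry counts must be at least 1", call. = FALSE)
  }
  if (cfg$pm_background < 0) stop("pm_background must be >= 0", call. = FALSE)
  if (cfg$pm_decay_length <= 0) {
    stop("pm_decay_length must be positive", call. = FALSE)
  }
  if (cfg$pm_noise_sd < 0) stop("pm_noise_sd must be >= 0", call. = FALSE)
  if (diff(cfg$elevation_range) < 0 || diff(cfg$pop_range) < 0) {
    stop("ranges must be non-decreasing", call. = FALSE)
  }
  structure(cfg, class = "region_config")
}

#' A planted exposure-disease effect
#'
#' The simulation truth: locality death counts are drawn as
#' Poisson(population x study_years x baseline_rate x exp(log_rate_slope x
#' score)) where score is the known exposure surface in \[0, 1\].
#'
#' @param baseline_rate Deaths per person per year at zero exposure (> 0
#'   unless deliberately degenerate).
#' @param log_rate_slope Log rate ratio per unit of exposure score.
#' @param study_years Length of the observation window in years (>= 1).
#' @return A list of class `planted_effect`.
#' @export
planted_effect <- function(baseline_rate, log_rate_slope = 0,
                           study_years = 8L) {
  if (baseline_rate < 0) stop("baseline_rate must be >= 0", call. = FALSE)
  if (study_years < 1) stop("study_years must be >= 1", call. = FALSE)
  structure(list(baseline_rate = baseline_rate,
                 log_rate_slope = log_rate_slope,
                 study_years = as.integer(study_years)),
            class = "planted_effect")
}

# Deterministic substream seed: one global seed fans out per component, so
# regenerating one component never shifts the stream of another.
sub_seed <- function(seed, component) {
  offsets <- c(elevation = 11L, rivers = 23L, industries = 37L, pm = 53L,
               localities = 71L, mortality = 97L, background = 113L,
               zones = 131L)
  k <- offsets[[component]]
  as.integer((as.double(seed) * 7919 + k * 104729) %% 2147483629)
}

blank_raster <- function(config, name = NULL) {
  raster_grid(matrix(0, config$grid_rows, config$grid_cols),
              origin = c(0, config$grid_rows * config$cell_size),
              cell_size = config$cell_size, name = name)
}

#' Simulate river polylines and industry points
#'
#' Rivers are monotone random walks spanning the grid west to east (x strictly
#' increasing, y a Gaussian walk reflected at the grid edges), which guarantees
#' a nontrivial distance gradient across the region. Industries are uniform
#' random points.
#'
#' @param config A [region_config()].
#' @return `sim_rivers()`: a list of n-by-2 vertex matrices.
#'   `sim_industries()`: a tibble with `id`, `x`, `y`.
#' @export
sim_rivers <- function(config) {
  extent_x <- config$grid_cols * config$cell_size
  extent_y <- config$grid_rows * config$cell_size
  set.seed(sub_seed(config$seed, "rivers"))
  lapply(seq_len(config$n_rivers), function(i) {
    n_pts <- config$grid_cols + 1L
    x <- seq(0, extent_x, length.out = n_pts)
    y <- numeric(n_pts)
    y[1] <- runif(1, 0.2, 0.8) * extent_y
    step <- rnorm(n_pts - 1L, 0, 0.8 * config$cell_size)
    for (j in 2:n_pts) {
      yj <- y[j - 1L] + step[j - 1L]
      # reflect at the extent so rivers stay inside the region
      if (yj < 0) yj <- -yj
      if (yj > extent_y) yj <- 2 * extent_y - yj
      y[j] <- yj
    }
    cbind(x = x, y = y)
  })
}

#' @rdname sim_rivers
#' @export
sim_industries <- function(config) {
  extent_x <- config$grid_cols * config$cell_size
  extent_y <- config$grid_rows * config$cell_size
  set.seed(sub_seed(config$seed, "industries"))
  tibble::tibble(
    id = sprintf("IND%02d", seq_len(config$n_industries)),
    x = runif(config$n_industries, 0.05, 0.95) * extent_x,
    y = runif(config$n_industries, 0.05, 0.95) * extent_y
  )
}

#' Generate the synthetic covariate stack
#'
#' Produces four aligned rasters on the configured grid:
#' * `elevation` - a sum of low-frequency cosine bumps with random phases,
#'   rescaled to `elevation_range` (smooth by construction);
#' * `dist_rivers` - exact planar Euclidean distance from each cell center to
#'   the nearest river polyline;
#' * `dist_industries` - distance to the nearest industry point;
#' * `pm25` - `pm_background + pm_industry_amplitude *
#'   exp(-dist_industries / pm_decay_length)` plus Gaussian cell noise.
#'
#' The same seed yields bit-identical output.
#'
#' @param config A [region_config()].
#' @param rivers,industries Optional feature layers; generated from `config`
#'   when omitted.
#' @return A [covariate_stack()] of the four layers, with the `rivers` and
#'   `industries` features attached as attributes.
#' @export
generate_covariates <- function(config, rivers = NULL, industries = NULL) {
  stopifnot(inherits(config, "region_config"))
  if (is.null(rivers)) rivers <- sim_rivers(config)
  if (is.null(industries)) industries <- sim_industries(config)
  template <- blank_raster(config)
  extent_x <- config$grid_cols * config$cell_size
  extent_y <- config$grid_rows * config$cell_size

  cc <- raster_cell_centers(template)

  # elevation: a handful of low-frequency cosine bumps, then rescale
  set.seed(sub_seed(config$seed, "elevation"))
  n_bumps <- 4L
  fx <- runif(n_bumps, 0.4, 1.6) / extent_x
  fy <- runif(n_bumps, 0.4, 1.6) / extent_y
  phase <- runif(n_bumps, 0, 2 * pi)
  amp <- runif(n_bumps, 0.5, 1)
  elev_raw <- rowSums(vapply(seq_len(n_bumps), function(k) {
    amp[k] * cos(2 * pi * (fx[k] * cc$x + fy[k] * cc$y) + phase[k])
  }, numeric(nrow(cc))))
  rng <- range(elev_raw)
  span <- if (diff(rng) > 0) diff(rng) else 1
  elev <- config$elevation_range[1] +
    (elev_raw - rng[1]) / span * diff(config$elevation_range)
  elevation <- template
  elevation$values <- matrix(elev, config$grid_rows, config$grid_cols)
  elevation$name <- "elevation"

  dist_rivers <- distance_raster(rivers, template)
  dist_rivers$name <- "dist_rivers"
  dist_industries <- distance_raster(industries, template)
  dist_industries$name <- "dist_industries"

  set.seed(sub_seed(config$seed, "pm"))
  noise <- if (config$pm_noise_sd > 0) {
    rnorm(length(template$values), 0, config$pm_noise_sd)
  } else {
    0
  }
  pm25 <- template
  pm25$values <- config$pm_background +
    config$pm_industry_amplitude *
      exp(-dist_industries$values / config$pm_decay_length) +
    matrix(noise, config$grid_rows, config$grid_cols)
  pm25$name <- "pm25"

  stack <- covariate_stack(list(elevation = elevation,
                                dist_rivers = dist_rivers,
                                dist_industries = dist_industries,
                                pm25 = pm25))
  attr(stack, "rivers") <- rivers
  attr(stack, "industries") <- industries
  stack
}

#' Generate populated localities
#'
#' Locality points are uniform inside the grid extent; populations are drawn
#' log-uniformly in `config$pop_range`.
#'
#' @param config A [region_config()].
#' @return A tibble with `locality_id`, `x`, `y`, `population`.
#' @export
generate_localities <- function(config) {
  stopifnot(inherits(config, "region_config"))
  extent_x <- config$grid_cols * config$cell_size
  extent_y <- config$grid_rows * config$cell_size
  set.seed(sub_seed(config$seed, "localities"))
  n <- config$n_localities
  tibble::tibble(
    locality_id = sprintf("L%03d", seq_len(n)),
    x = runif(n, 0, extent_x),
    y = runif(n, 0, extent_y),
    population = round(exp(runif(n, log(config$pop_range[1]),
                                 log(config$pop_range[2]))))
  )
}

#' The known exposure surface of a synthetic region
#'
#' A deterministic ground-truth suitability score in \[0, 1\]: a convex
#' combination of exponential proximity to industries and to rivers, rescaled
#' to the unit interval. Downstream stages try to recover zones of this
#' surface; it is the simulation truth, not a fitted quantity.
#'
#' @param stack A [covariate_stack()] holding `dist_rivers` and
#'   `dist_industries`.
#' @param decay e-folding distance in metres for both proximity terms.
#' @param w_industry Weight on industry proximity (rivers get `1 - w_industry`).
#' @return A [raster_grid()] with values in \[0, 1\].
#' @export
exposure_surface <- function(stack, decay = 2000, w_industry = 0.6) {
  d_ind <- stack$layers$dist_industries
  d_riv <- stack$layers$dist_rivers
  stopifnot(!is.null(d_ind), !is.null(d_riv))
  s <- w_industry * exp(-d_ind$values / decay) +
    (1 - w_industry) * exp(-d_riv$values / decay)
  rng <- range(s, na.rm = TRUE)
  span <- if (diff(rng) > 0) diff(rng) else 1
  out <- d_ind
  out$values <- (s - rng[1]) / span
  out$name <- "exposure_score"
  out
}

#' Simulate locality mortality under a planted effect
#'
#' For each locality and study year, deaths are drawn as
#' Poisson(population x baseline_rate x exp(log_rate_slope x score)), where
#' score is the exposure surface value at the locality's cell. Poisson counts
#' suit the rare-event rate framework used for crude mortality rates.
#'
#' @param localities Tibble with `locality_id`, `x`, `y`, `population`.
#' @param exposure_score A [raster_grid()] with values in \[0, 1\].
#' @param effect A [planted_effect()].
#' @param seed Integer seed.
#' @param cause_code ICD-10 cause attached to the records.
#' @param first_year Calendar year of the first simulated year.
#' @return A tibble with `cause_code`, `locality_id`, `year`, `deaths`.
#' @export
simulate_mortality <- function(localities, exposure_score, effect,
                               seed = 1L, cause_code = "I259",
                               first_year = 2013L) {
  stopifnot(inherits(effect, "planted_effect"),
            inherits(exposure_score, "raster_grid"))
  loc <- raster_locate(exposure_score, localities$x, localities$y)
  if (anyNA(loc$row)) {
    bad <- localities$locality_id[is.na(loc$row)]
    stop("localities outside the raster extent: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  score <- loc$value
  if (anyNA(score) || any(score < 0 | score > 1)) {
    stop("exposure score must be defined in [0, 1] at every locality cell",
         call. = FALSE)
  }
  mu_year <- localities$population * effect$baseline_rate *
    exp(effect$log_rate_slope * score)
  set.seed(sub_seed(seed, "mortality"))
  years <- first_year + seq_len(effect$study_years) - 1L
  tidyr::expand_grid(locality_id = localities$locality_id, year = years) |>
    dplyr::left_join(tibble::tibble(locality_id = localities$locality_id,
                                    mu = mu_year),
                     by = "locality_id") |>
    dplyr::mutate(cause_code = cause_code,
                  deaths = rpois(dplyr::n(), .data$mu)) |>
    dplyr::select("cause_code", "locality_id", "year", "deaths")
}

#' Simulate a full synthetic region
#'
#' Bundles covariates, localities, the known exposure surface, and mortality
#' counts under one seed.
#'
#' @param config A [region_config()].
#' @param effect A [planted_effect()].
#' @return A list with `config`, `stack`, `exposure`, `localities`,
#'   `mortality`.
#' @export
simulate_region <- function(config = region_config(),
                            effect = planted_effect(1.5e-5,
                                                    log_rate_slope = log(6))) {
  stack <- generate_covariates(config)
  exposure <- exposure_surface(stack)
  localities <- generate_localities(config)
  mortality <- simulate_mortality(localities, exposure, effect,
                                  seed = config$seed,
                                  cause_code = config$cause_code)
  list(config = config, stack = stack, exposure = exposure,
       localities = localities, mortality = mortality)
}

#' Simulate locality case counts with an exact planted odds ratio
#'
#' Given localities already assigned to exposure zones, plants a per-person
#' case probability that makes the population-level odds ratio of the exposed
#' zones against the rest exactly `target_or`: if `mu_u` is the unexposed
#' per-person probability over the study window, the exposed probability is
#' the odds-transform `mu_e = OR * odds_u / (1 + OR * odds_u)`. Counts are
#' Poisson draws with these means.
#'
#' @param localities Tibble with `locality_id`, `population`, `zone`.
#' @param exposed_zones Integer vector of zone labels counted as exposed.
#' @param target_or True odds ratio (exposed vs unexposed).
#' @param mu_unexposed Per-person case probability over the window in the
#'   unexposed zones.
#' @param seed Integer seed.
#' @return `localities` with a `cases` column added.
#' @export
simulate_zone_mortality <- function(localities, exposed_zones, target_or,
                                    mu_unexposed, seed = 1L) {
  stopifnot(all(c("population", "zone") %in% names(localities)),
            mu_unexposed > 0, mu_unexposed < 1, target_or > 0)
  odds_u <- mu_unexposed / (1 - mu_unexposed)
  odds_e <- target_or * odds_u
  mu_e <- odds_e / (1 + odds_e)
  mu <- ifelse(localities$zone %in% exposed_zones, mu_e, mu_unexposed)
  set.seed(sub_seed(seed, "mortality"))
  dplyr::mutate(localities, cases = rpois(dplyr::n(), .data$population * mu))
}

#' Simulate an end-to-end zone-association study
#'
#' Builds a synthetic region, classifies its known exposure surface into
#' `k` zones by Fisher-Jenks natural breaks, assigns localities to zones, and
#' plants a case process whose true odds ratio (top zone vs the rest) is
#' exactly `target_or`. The unexposed per-person probability is solved from
#' the realized populations so the expected total case count equals
#' `expected_cases`; both the odds ratio and the expected case yield are
#' design parameters of the study, fixed before any data are drawn.
#'
#' @param config A [region_config()].
#' @param target_or True odds ratio of the top exposure zone vs the rest.
#' @param expected_cases Expected total number of cases across the region.
#' @param k Number of exposure zones.
#' @param seed Seed for the case draws (region geometry uses `config$seed`).
#' @return A list: `zones` (a `zone_map`), `localities` (with `zone` and
#'   `cases`), and `truth` (`or`, `af_percent`, `mu_unexposed`, `mu_exposed`).
#' @export
simulate_association_study <- function(config = region_config(),
                                       target_or = 4, expected_cases = 200,
                                       k = 3, seed = config$seed) {
  stack <- generate_covariates(config)
  exposure <- exposure_surface(stack)
  breaks <- fisher_jenks(as.vector(exposure$values), k = k)
  zones <- classify_zones(exposure, breaks)
  localities <- generate_localities(config)
  zl <- raster_locate(zones$raster, localities$x, localities$y)
  localities$zone <- as.integer(zl$value)

  exposed <- localities$zone == k
  pop_e <- sum(localities$population[exposed])
  pop_u <- sum(localities$population[!exposed])
  if (pop_e == 0 || pop_u == 0) {
    stop("degenerate zone assignment: one side of the contrast is empty",
         call. = FALSE)
  }
  expected_total <- function(mu_u) {
    odds_e <- target_or * mu_u / (1 - mu_u)
    mu_e <- odds_e / (1 + odds_e)
    pop_u * mu_u + pop_e * mu_e - expected_cases
  }
  mu_u <- stats::uniroot(expected_total, c(1e-9, 0.2), tol = 1e-12)$root
  odds_e <- target_or * mu_u / (1 - mu_u)
  mu_e <- odds_e / (1 + odds_e)

  localities <- simulate_zone_mortality(localities, exposed_zones = k,
                                        target_or = target_or,
                                        mu_unexposed = mu_u, seed = seed)
  list(
    zones = zones, localities = localities,
    truth = list(or = target_or,
                 af_percent = 100 * (target_or - 1) / target_or,
                 mu_unexposed = mu_u, mu_exposed = mu_e)
  )
}

#' Write a simulated region to disk
#'
#' Rasters go out as Arc/Info ASCII grids, vectors as GeoJSON, and the
#' mortality and population tables as CSV (`cause_code, locality_id, year,
#' deaths` and `locality_id, population`).
#'
#' @param region Output of [simulate_region()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_region <- function(region, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(region$stack$layers)) {
    write_ascii_grid(region$stack$layers[[nm]], file.path(dir,
                                                          paste0(nm, ".asc")))
  }
  write_ascii_grid(region$exposure, file.path(dir, "exposure_score.asc"))
  write_geojson_lines(attr(region$stack, "rivers"),
                      file.path(dir, "rivers.geojson"))
  write_geojson_points(attr(region$stack, "industries"),
                       file.path(dir, "industries.geojson"))
  write_geojson_points(region$localities, file.path(dir,
                                                    "localities.geojson"))
  write.csv(region$mortality, file.path(dir, "mortality.csv"),
            row.names = FALSE)
  write.csv(region$localities[c("locality_id", "population")],
            file.path(dir, "population.csv"), row.names = FALSE)
  invisible(dir)
}
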