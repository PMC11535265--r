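#' Summarise cases and population by exposure zone
#'
#' Assigns each locality to the zone of its containing cell and tallies
#' cases, population, the crude rate per 100,000, zone area (valid cell
#' count times cell area, km2) and locality count per zone. Zone totals
#' conserve the study totals.
#'
#' @param zones A `zone_map` from [classify_zones()].
#' @param localities Tibble with `locality_id`, `x`, `y`, `population`,
#'   `cases` (or pass `mortality` to tally cases from records).
#' @param mortality Optional tibble with `locality_id`, `deaths`; summed per
#'   locality into `cases` when `localities` has no `cases` column.
#' @return A tibble with one row per zone: `zone`, `cases`, `population`,
#'   `rate`, `area_km2`, `n_localities`.
#' @export
zonal_summary <- function(zones, localities, mortality = NULL) {
  stopifnot(inherits(zones, "zone_map"))
  if (!"cases" %in% names(localities)) {
    if (is.null(mortality)) {
      stop("localities need a `cases` column or a `mortality` table",
           call. = FALSE)
    }
    tal <- mortality |>
      dplyr::group_by(.data$locality_id) |>
      dplyr::summarise(cases = sum(.data$deaths), .groups = "drop")
    localities <- dplyr::left_join(localities, tal, by = "locality_id") |>
      dplyr::mutate(cases = dplyr::coalesce(.data$cases, 0L))
  }
  loc <- raster_locate(zones$raster, localities$x, localities$y)
  if (anyNA(loc$value)) {
    bad <- localities$locality_id[is.na(loc$value)]
    stop("localities on nodata or outside the zone map: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  localities$zone <- as.integer(loc$value)

  cell_area_km2 <- zones$raster$cell_size^2 / 1e6
  area <- tibble::tibble(zone = seq_len(zones$k)) |>
    dplyr::mutate(area_km2 = vapply(.data$zone, function(z) {
      sum(zones$raster$values == z, na.rm = TRUE) * cell_area_km2
    }, numeric(1)))

  localities |>
    dplyr::group_by(.data$zone) |>
    dplyr::summarise(cases = sum(.data$cases),
                     population = sum(.data$population),
                     n_localities = dplyr::n(), .groups = "drop") |>
    dplyr::right_join(area, by = "zone") |>
    dplyr::mutate(dplyr::across(c("cases", "population", "n_localities"),
                                \(v) dplyr::coalesce(v, 0L)),
                  rate = dplyr::if_else(.data$population > 0,
                                        1e5 * .data$cases / .data$population,
                                        NA_real_)) |>
    dplyr::select("zone", "cases", "population", "rate", "area_km2",
                  "n_localities") |>
    dplyr::arrange(.data$zone)
}

#' Build a 2x2 exposure-by-outcome table from a zonal summary
#'
#' `A` = cases in exposed zones, `B` = cases in unexposed zones, `C` =
#' noncases (population minus cases) in exposed zones, `D` = noncases in
#' unexposed zones.
#'
#' @param summary A [zonal_summary()] tibble.
#' @param exposed,unexposed Disjoint, non-empty sets of zone labels.
#' @return A list of class `contingency_2x2` with `A`, `B`, `C`, `D` and the
#'   contrast label.
#' @export
contingency_2x2 <- function(summary, exposed, unexposed) {
  if (!length(exposed) || !length(unexposed)) {
    stop("exposed and unexposed zone sets must be non-empty", call. = FALSE)
  }
  if (length(intersect(exposed, unexposed))) {
    stop("exposed and unexposed zone sets overlap", call. = FALSE)
  }
  se <- summary[summary$zone %in% exposed, ]
  su <- summary[summary$zone %in% unexposed, ]
  a <- sum(se$cases); b <- sum(su$cases)
  structure(list(
    A = a, B = b,
    C = sum(se$population) - a, D = sum(su$population) - b,
    contrast = sprintf("zone %s vs zone %s",
                       paste(sort(exposed), collapse = "+"),
                       paste(sort(unexposed), collapse = "+"))
  ), class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  cat(sprintf("<contingency_2x2> %s\n", x$contrast))
  cat(sprintf("  cases    exposed %g | unexposed %g\n", x$A, x$B))
  cat(sprintf("  noncases exposed %g | unexposed %g\n", x$C, x$D))
  invisible(x)
}

#' Odds ratio of a 2x2 table
#'
#' `OR = A * D / (B * C)`. A value below 1 indicates a protective
#' association; above 1, a positive association between exposure and
#' outcome. When a cell is zero the OR is undefined; with
#' `haldane = TRUE` the Haldane-Anscombe correction adds 0.5 to every cell
#' and flags the result.
#'
#' @param t A [contingency_2x2()].
#' @param haldane Apply the 0.5 continuity correction when a cell is zero.
#' @return The OR, with attribute `"haldane"` indicating whether the
#'   correction was applied.
#' @export
odds_ratio <- function(t, haldane = FALSE) {
  stopifnot(inherits(t, "contingency_2x2"))
  cells <- c(t$A, t$B, t$C, t$D)
  if (any(cells < 0)) stop("negative cell count", call. = FALSE)
  corrected <- FALSE
  if (any(cells == 0)) {
    if (haldane) {
      cells <- cells + 0.5
      corrected <- TRUE
    } else if (t$B == 0 || t$C == 0) {
      stop("zero cell: odds ratio undefined (use haldane = TRUE for the ",
           "0.5 continuity correction)", call. = FALSE)
    }
  }
  or <- cells[1] * cells[4] / (cells[2] * cells[3])
  attr(or, "haldane") <- corrected
  or
}

#' Confidence interval for an odds ratio
#'
#' Default `"woolf"` (log scale): `exp(log OR +/- z * sqrt(1/A + 1/B + 1/C +
#' 1/D))`, symmetric about the OR in log space. The `"linear"` option
#' returns `OR +/- z * SE` with `SE = OR * sqrt(1/A + 1/B + 1/C + 1/D)`,
#' arithmetically symmetric about the OR.
#'
#' @param t A [contingency_2x2()].
#' @param method `"woolf"` (default) or `"linear"`.
#' @param alpha Two-sided significance level (default 0.05 for 95% CI).
#' @param haldane Apply the 0.5 correction to zero cells.
#' @return A list with `or`, `lower`, `upper`, `method`, `alpha`.
#' @export
odds_ratio_ci <- function(t, method = c("woolf", "linear"), alpha = 0.05,
                          haldane = FALSE) {
  method <- match.arg(method)
  or <- odds_ratio(t, haldane = haldane)
  corrected <- attr(or, "haldane")
  or <- as.numeric(or)
  cells <- c(t$A, t$B, t$C, t$D)
  if (corrected) cells <- cells + 0.5
  if (any(cells == 0)) stop("zero cell: CI undefined", call. = FALSE)
  se_log <- sqrt(sum(1 / cells))
  z <- qnorm(1 - alpha / 2)
  if (method == "woolf") {
    lower <- exp(log(or) - z * se_log)
    upper <- exp(log(or) + z * se_log)
  } else {
    se <- or * se_log
    lower <- or - z * se
    upper <- or + z * se
  }
  list(or = or, lower = lower, upper = upper, method = method,
       alpha = alpha, haldane = corrected)
}

#' Attributable fraction in the exposed
#'
#' `AF = 100 * (OR - 1) / OR` percent, the share of exposed cases
#' attributable to the exposure under the rare-disease approximation.
#' Protective associations (OR < 1) report 0 with a flag. An RR-based
#' variant uses the same arithmetic on the relative risk.
#'
#' @param or Odds ratio (or relative risk for the RR-based variant).
#' @return AF in percent, in \[0, 100); attribute `"protective"` flags
#'   OR < 1 inputs.
#' @export
#' @examples
#' attributable_fraction(3.37) # 70.3
#' attributable_fraction(4.79) # 79.1
attributable_fraction <- function(or) {
  if (any(or < 0, na.rm = TRUE)) stop("OR must be non-negative",
                                      call. = FALSE)
  protective <- or < 1
  af <- ifelse(protective, 0, 100 * (or - 1) / or)
  attr(af, "protective") <- protective
  af
}

#' Relative risk between exposed and unexposed zones
#'
#' The ratio of the crude incidence rates (per the common scale, which
#' cancels): `RR = rate_exposed / rate_unexposed`.
#'
#' @param summary A [zonal_summary()] tibble.
#' @param exposed,unexposed Disjoint zone sets.
#' @return The relative risk.
#' @export
relative_risk <- function(summary, exposed, unexposed) {
  t <- contingency_2x2(summary, exposed, unexposed)
  pop_e <- t$A + t$C
  pop_u <- t$B + t$D
  if (pop_e <= 0 || pop_u <= 0) {
    stop("empty population on one side of the contrast", call. = FALSE)
  }
  rate_u <- t$B / pop_u
  if (rate_u == 0) {
    stop("unexposed rate is zero: relative risk undefined", call. = FALSE)
  }
  (t$A / pop_e) / rate_u
}

#' Zone-contrast association measures
#'
#' One-stop computation for a zone contrast: the 2x2 table, odds ratio with
#' confidence interval, relative risk, and attributable fraction in the
#' exposed.
#'
#' @param summary A [zonal_summary()] tibble.
#' @param exposed,unexposed Disjoint zone sets (defaults: top zone vs the
#'   rest).
#' @param ci_method `"woolf"` or `"linear"`.
#' @param alpha Significance level for the CI.
#' @param haldane Apply the 0.5 correction to zero cells.
#' @return An object of class `association_result`.
#' @export
zone_association <- function(summary, exposed = max(summary$zone),
                             unexposed = setdiff(summary$zone, exposed),
                             ci_method = c("woolf", "linear"),
                             alpha = 0.05, haldane = FALSE) {
  ci_method <- match.arg(ci_method)
  t <- contingency_2x2(summary, exposed, unexposed)
  ci <- odds_ratio_ci(t, method = ci_method, alpha = alpha,
                      haldane = haldane)
  rr <- tryCatch(relative_risk(summary, exposed, unexposed),
                 error = function(e) NA_real_)
  af <- attributable_fraction(ci$or)
  structure(list(
    table = t, or = ci$or, ci_lower = ci$lower, ci_upper = ci$upper,
    ci_method = ci_method, alpha = alpha, haldane = ci$haldane,
    relative_risk = rr, af_percent = as.numeric(af),
    protective = as.logical(attr(af, "protective")),
    contrast = t$contrast
  ), class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("<association_result> %s\n", x$contrast))
  cat(sprintf("  OR %.3f (%d%% CI %.3f-%.3f, %s%s)\n", x$or,
              round(100 * (1 - x$alpha)), x$ci_lower, x$ci_upper,
              x$ci_method, if (x$haldane) ", Haldane-corrected" else ""))
  cat(sprintf("  RR %.3f | AF %.1f%%%s\n", x$relative_risk, x$af_percent,
              if (x$protective) " (protective; AF floored at 0)" else ""))
  invisible(x)
}

#' @export
tidy.association_result <- function(x, ...) {
  tibble::tibble(
    contrast = x$contrast,
    A = x$table$A, B = x$table$B, C = x$table$C, D = x$table$D,
    or = x$or, ci_lower = x$ci_lower, ci_upper = x$ci_upper,
    ci_method = x$ci_method, relative_risk = x$relative_risk,
    af_percent = x$af_percent, protective = x$protective,
    haldane = x$haldane
  )
}

#' @export
glance.association_result <- function(x, ...) tidy(x)

#' Forest-style plot of association results
#'
#' @param object An `association_result` or a list of them.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.association_result <- function(object, ...) {
  plot_associations(list(object))
}

#' @rdname autoplot.association_result
#' @param results A list of `association_result` objects.
#' @export
plot_associations <- function(results) {
  df <- dplyr::bind_rows(lapply(results, tidy))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$or, y = .data$contrast)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_lower,
                                          xmax = .data$ci_upper)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (log scale)", y = NULL)
}
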