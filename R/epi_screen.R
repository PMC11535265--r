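#' Crude mortality rate per `scale` persons
#'
#' The crude rate is `scale * cases / population`, with person-time
#' approximated as the census population over the study window. No rounding
#' is applied; rounding for reports is a formatting concern.
#'
#' @param cases Non-negative case counts (vectorized).
#' @param population Positive population denominators.
#' @param scale Rate scale in persons (default 100,000).
#' @return Numeric vector of rates.
#' @export
#' @examples
#' mortality_rate(201, 515726) # 38.97 per 100,000
mortality_rate <- function(cases, population, scale = 1e5) {
  if (any(population <= 0, na.rm = TRUE)) {
    stop("population must be positive", call. = FALSE)
  }
  if (any(cases < 0, na.rm = TRUE)) {
    stop("cases must be non-negative", call. = FALSE)
  }
  scale * cases / population
}

#' Mortality-rate ratio
#'
#' Ratio of a local crude rate to a reference (e.g. national) rate for the
#' same cause and period. Dimensionless, invariant to the common rate scale.
#'
#' @param local,reference Rates on a common scale (vectorized).
#' @return Numeric vector of ratios.
#' @export
mortality_rate_ratio <- function(local, reference) {
  if (any(reference <= 0, na.rm = TRUE)) {
    stop("reference rate must be positive", call. = FALSE)
  }
  local / reference
}

#' Normalize ICD-10 codes
#'
#' Accepts dotted or undotted codes in any case and returns undotted
#' uppercase (`"i25.9"` -> `"I259"`).
#'
#' @param code Character vector of ICD-10 codes.
#' @return Normalized character vector.
#' @export
normalize_icd10 <- function(code) {
  gsub(".", "", toupper(trimws(code)), fixed = TRUE)
}

#' Per-cause rate table
#'
#' Aggregates a mortality table over localities and years and attaches the
#' crude rate per `scale` persons.
#'
#' @param mortality Tibble with `cause_code`, `deaths`, and optionally
#'   `locality_id`, `year`.
#' @param population Total population of the study area (single number) or a
#'   tibble with `locality_id`, `population` to be summed.
#' @param scale Rate scale (persons).
#' @return A tibble with `cause_code`, `cases`, `population`, `scale`,
#'   `rate`.
#' @export
rate_table <- function(mortality, population, scale = 1e5) {
  pop <- if (is.data.frame(population)) sum(population$population)
    else as.numeric(population)
  mortality |>
    dplyr::mutate(cause_code = normalize_icd10(.data$cause_code)) |>
    dplyr::group_by(.data$cause_code) |>
    dplyr::summarise(cases = sum(.data$deaths), .groups = "drop") |>
    dplyr::mutate(population = pop, scale = scale,
                  rate = mortality_rate(.data$cases, pop, scale)) |>
    dplyr::arrange(dplyr::desc(.data$rate))
}

#' Per-cause, per-year MRR series
#'
#' Joins local and reference series on cause and year and computes the
#' mortality-rate ratio for every year. Years where the reference records
#' zero deaths get a missing MRR (the ratio is undefined, not infinite).
#'
#' @param local,reference Tibbles with one row per cause and year:
#'   `cause_code`, `year`, `deaths`, `population` (the series' denominator
#'   for that year).
#' @param scale Rate scale (cancels in the ratio; kept for reported rates).
#' @return A long tibble with per-year local/reference rates and `mrr`.
#' @export
mrr_table <- function(local, reference, scale = 1e5) {
  norm <- function(d) {
    d <- dplyr::mutate(d, cause_code = normalize_icd10(.data$cause_code))
    if (anyDuplicated(d[c("cause_code", "year")])) {
      stop("expected one row per (cause_code, year)", call. = FALSE)
    }
    d
  }
  dplyr::inner_join(
    norm(local),
    norm(reference) |>
      dplyr::rename(ref_deaths = "deaths", ref_population = "population"),
    by = c("cause_code", "year")
  ) |>
    dplyr::mutate(
      rate = mortality_rate(.data$deaths, .data$population, scale),
      ref_rate = mortality_rate(.data$ref_deaths, .data$ref_population,
                                scale),
      mrr = dplyr::if_else(.data$ref_deaths > 0,
                           .data$rate / .data$ref_rate, NA_real_)
    )
}

#' Screen causes of death by recurrent excess mortality
#'
#' Restricts to the `top_k` causes by total local deaths, counts for each the
#' number of years with MRR strictly above 1 against the reference series,
#' and selects causes reaching `min_years` such years. An exclusion list
#' (e.g. diabetes, whose aetiology is not pollution-specific) is honored:
#' excluded causes are reported but never selected. Ranking is
#' permutation-stable: ties in the year count break by total deaths, then by
#' cause code.
#'
#' @param local,reference Tibbles with `cause_code`, `year`, `deaths`,
#'   `population` (population may repeat per cause-year).
#' @param min_years Minimum number of MRR > 1 years for selection.
#' @param top_k Number of causes (by total local deaths) considered.
#' @param exclude Character vector of ICD-10 codes (or prefixes, e.g.
#'   `"E10-E14"` ranges are expanded on the 3-character stem) never selected.
#' @param scale Rate scale.
#' @return A tibble with one row per considered cause: `cause_code`,
#'   `total_deaths`, `n_years`, `n_years_mrr_gt1`, `excluded`, `selected`,
#'   ranked; the full per-year series is attached as attribute `"mrr"`.
#' @export
screen_causes <- function(local, reference, min_years = 10L, top_k = 20L,
                          exclude = NULL, scale = 1e5) {
  series <- mrr_table(local, reference, scale = scale)
  if (nrow(series) == 0L) {
    out <- tibble::tibble(cause_code = character(), total_deaths = numeric(),
                          n_years = integer(), n_years_mrr_gt1 = integer(),
                          excluded = logical(), selected = logical())
    attr(out, "mrr") <- series
    return(out)
  }
  excl <- expand_icd_ranges(exclude)
  per_cause <- series |>
    dplyr::group_by(.data$cause_code) |>
    dplyr::summarise(
      total_deaths = sum(.data$deaths),
      n_years = dplyr::n_distinct(.data$year),
      n_years_mrr_gt1 = sum(.data$mrr > 1, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$total_deaths), .data$cause_code) |>
    head(top_k) |>
    dplyr::mutate(
      excluded = icd_matches(.data$cause_code, excl),
      selected = !.data$excluded & .data$n_years_mrr_gt1 >= min_years
    ) |>
    dplyr::arrange(dplyr::desc(.data$n_years_mrr_gt1),
                   dplyr::desc(.data$total_deaths), .data$cause_code)
  attr(per_cause, "mrr") <- series
  per_cause
}

# Expand "E10-E14" style ranges on the 3-character stem; pass plain codes
# through normalized.
expand_icd_ranges <- function(exclude) {
  if (is.null(exclude) || !length(exclude)) return(character())
  out <- lapply(exclude, function(e) {
    e <- toupper(trimws(e))
    m <- regmatches(e, regexec("^([A-Z])([0-9]{2})-([A-Z])([0-9]{2})$", e))[[1]]
    if (length(m) == 5L && m[2] == m[4]) {
      sprintf("%s%02d", m[2], as.integer(m[3]):as.integer(m[5]))
    } else {
      normalize_icd10(e)
    }
  })
  unique(unlist(out))
}

# TRUE where a code equals or extends (as a prefix) an excluded stem.
icd_matches <- function(code, stems) {
  if (!length(stems)) return(rep(FALSE, length(code)))
  code <- normalize_icd10(code)
  vapply(code, function(cc) {
    any(vapply(stems, function(s) startsWith(cc, s), logical(1)))
  }, logical(1), USE.NAMES = FALSE)
}
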