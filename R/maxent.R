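#' Build a maximum-entropy feature set over a covariate stack
#'
#' Features are derived from covariates scaled into \[0, 1\] using the
#' covariate's min/max over valid cells:
#' * `linear`: the scaled covariate `z`;
#' * `quadratic`: `z^2`;
#' * `product`: `z_a * z_b` for every covariate pair;
#' * `hinge`: for each of `hinge_knots` equally spaced interior knots `t`,
#'   both orientations — forward `max(0, (z - t) / (1 - t))` and reverse
#'   `max(0, (t - z) / t)` — so a covariate contributes `2 * hinge_knots`
#'   hinge features.
#'
#' All features lie in \[0, 1\] on valid cells. Constant covariates cannot be
#' scaled; their features are dropped with a warning.
#'
#' @param stack A (screened) [covariate_stack()].
#' @param classes Character subset of `c("linear", "quadratic", "product",
#'   "hinge")`.
#' @param hinge_knots Number of interior hinge knots per covariate.
#' @return An object of class `feature_set`: a tibble of feature definitions
#'   plus the per-covariate scaling constants.
#' @export
build_features <- function(stack,
                           classes = c("linear", "quadratic", "hinge"),
                           hinge_knots = 10L) {
  stopifnot(inherits(stack, "covariate_stack"))
  classes <- match.arg(classes, c("linear", "quadratic", "product", "hinge"),
                       several.ok = TRUE)
  df <- as_tibble(stack)
  covs <- names(stack$layers)
  scaling <- purrr::map_dfr(covs, function(nm) {
    v <- df[[nm]][df$valid]
    tibble::tibble(covariate = nm, cov_min = min(v), cov_max = max(v))
  })
  flat <- scaling$covariate[scaling$cov_max == scaling$cov_min]
  if (length(flat)) {
    warning("constant covariate(s) dropped from the feature set: ",
            paste(flat, collapse = ", "), call. = FALSE)
    covs <- setdiff(covs, flat)
  }
  if (!length(covs)) stop("no non-constant covariates left", call. = FALSE)

  defs <- list()
  if ("linear" %in% classes) {
    defs <- c(defs, list(tibble::tibble(
      feature = paste0("lin_", covs), class = "linear",
      covariate = covs, covariate2 = NA_character_, knot = NA_real_)))
  }
  if ("quadratic" %in% classes) {
    defs <- c(defs, list(tibble::tibble(
      feature = paste0("quad_", covs), class = "quadratic",
      covariate = covs, covariate2 = NA_character_, knot = NA_real_)))
  }
  if ("product" %in% classes && length(covs) >= 2L) {
    pairs <- utils::combn(covs, 2L)
    defs <- c(defs, list(tibble::tibble(
      feature = paste0("prod_", pairs[1, ], "_x_", pairs[2, ]),
      class = "product", covariate = pairs[1, ], covariate2 = pairs[2, ],
      knot = NA_real_)))
  }
  if ("hinge" %in% classes && hinge_knots >= 1L) {
    knots <- seq_len(hinge_knots) / (hinge_knots + 1)
    defs <- c(defs, list(
      tidyr::expand_grid(covariate = covs, knot = knots) |>
        dplyr::mutate(feature = sprintf("hingeF_%s_%.3f", .data$covariate,
                                        .data$knot),
                      class = "hinge_forward", covariate2 = NA_character_) |>
        dplyr::select("feature", "class", "covariate", "covariate2", "knot"),
      tidyr::expand_grid(covariate = covs, knot = knots) |>
        dplyr::mutate(feature = sprintf("hingeR_%s_%.3f", .data$covariate,
                                        .data$knot),
                      class = "hinge_reverse", covariate2 = NA_character_) |>
        dplyr::select("feature", "class", "covariate", "covariate2", "knot")
    ))
  }
  structure(list(defs = dplyr::bind_rows(defs),
                 scaling = scaling[scaling$covariate %in% covs, ]),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d features over %d covariates (%s)\n",
              nrow(x$defs), nrow(x$scaling),
              paste(unique(x$defs$class), collapse = ", ")))
  invisible(x)
}

# Evaluate the feature matrix for covariate values (tibble with one column
# per covariate). Scaled covariates are clamped to [0, 1] so projection
# outside the training range stays bounded.
feature_matrix <- function(features, values) {
  sc <- features$scaling
  z <- vapply(sc$covariate, function(nm) {
    i <- match(nm, sc$covariate)
    pmin(pmax((values[[nm]] - sc$cov_min[i]) /
                (sc$cov_max[i] - sc$cov_min[i]), 0), 1)
  }, numeric(nrow(values)))
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L,
                                   dimnames = list(NULL, sc$covariate))
  d <- features$defs
  out <- matrix(0, nrow(values), nrow(d),
                dimnames = list(NULL, d$feature))
  for (j in seq_len(nrow(d))) {
    zc <- z[, d$covariate[j]]
    out[, j] <- switch(
      d$class[j],
      linear = zc,
      quadratic = zc^2,
      product = zc * z[, d$covariate2[j]],
      hinge_forward = pmax(0, (zc - d$knot[j]) / (1 - d$knot[j])),
      hinge_reverse = pmax(0, (d$knot[j] - zc) / d$knot[j])
    )
  }
  out
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Fit a presence-background maximum-entropy model
#'
#' Finds the Gibbs distribution over background cells that maximizes the
#' L1-regularized log likelihood of the presence sample,
#' `mean_presence(f %*% lambda) - log Z(lambda) - sum(beta * |lambda|)`,
#' by cyclic coordinate ascent: each coordinate takes a soft-thresholded
#' Newton step with backtracking, so the regularized training gain is
#' non-decreasing across accepted steps. Per-feature regularization is
#' `beta_j = beta_multiplier * s_j / sqrt(m)` with `s_j` the background
#' standard deviation of feature `j` and `m` the presence count.
#'
#' @param stack A [covariate_stack()] (after collinearity screening).
#' @param presence Tibble of presence locations: either `x`, `y` coordinates
#'   or `row`, `col` cell indices.
#' @param features A [build_features()] result; defaults to linear +
#'   quadratic + hinge(10) over the stack.
#' @param beta_multiplier Global multiplier on the regularization schedule;
#'   `0` disables regularization.
#' @param max_background Background cap: all valid cells when fewer,
#'   otherwise a seeded uniform sample of this size.
#' @param seed Seed for background sampling.
#' @param max_cycles,tol Convergence controls: stop when the regularized gain
#'   improves by less than `tol` over a full cycle, or after `max_cycles`.
#' @return An object of class `maxent_model`.
#' @export
maxent_fit <- function(stack, presence, features = NULL,
                       beta_multiplier = 1, max_background = 10000L,
                       seed = 42L, max_cycles = 500L, tol = 1e-6) {
  stopifnot(inherits(stack, "covariate_stack"))
  if (is.null(features)) features <- build_features(stack)
  df <- as_tibble(stack)
  covs <- features$scaling$covariate

  # presence cells
  if (all(c("row", "col") %in% names(presence))) {
    pr <- presence[c("row", "col")]
  } else if (all(c("x", "y") %in% names(presence))) {
    loc <- raster_locate(stack$grid, presence$x, presence$y)
    if (anyNA(loc$row)) {
      stop("presence location(s) outside the raster extent (rows ",
           paste(which(is.na(loc$row)), collapse = ", "), ")", call. = FALSE)
    }
    pr <- loc[c("row", "col")]
  } else {
    stop("presence needs x/y or row/col columns", call. = FALSE)
  }
  if (nrow(pr) < 1L) stop("need at least one presence cell", call. = FALSE)
  nr <- nrow(stack$grid$values)
  p_idx <- pr$row + (pr$col - 1L) * nr
  p_vals <- df[p_idx, covs, drop = FALSE]
  if (anyNA(p_vals)) {
    bad <- which(!stats::complete.cases(p_vals))
    stop("non-finite covariates at presence cell(s) (row, col): ",
         paste(sprintf("(%d, %d)", pr$row[bad], pr$col[bad]),
               collapse = " "), call. = FALSE)
  }

  # background: all valid cells, or a seeded sample
  valid_idx <- which(df$valid)
  if (length(valid_idx) > max_background) {
    set.seed(seed)
    bg_idx <- sort(sample(valid_idx, max_background))
  } else {
    bg_idx <- valid_idx
  }
  n <- length(bg_idx)
  if (n < 2L) stop("background has fewer than 2 valid cells", call. = FALSE)

  Fb <- feature_matrix(features, df[bg_idx, covs, drop = FALSE])
  Fp <- feature_matrix(features, p_vals)
  m <- nrow(Fp)
  pbar <- colMeans(Fp)
  s_bg <- apply(Fb, 2L, sd)
  beta <- beta_multiplier * s_bg / sqrt(m)

  J <- ncol(Fb)
  lambda <- numeric(J)
  eta <- numeric(n)
  reg_obj <- function(lam, et) {
    sum(pbar * lam) - log_sum_exp(et) - sum(beta * abs(lam))
  }
  obj0 <- reg_obj(lambda, eta)         # = -log(n)
  obj <- obj0
  trace <- vector("list", 0L)
  cycles <- 0L
  converged <- FALSE

  for (cycle in seq_len(max_cycles)) {
    cycles <- cycle
    obj_cycle_start <- obj
    for (j in seq_len(J)) {
      w <- exp(eta - max(eta))
      q <- w / sum(w)
      fj <- Fb[, j]
      e1 <- sum(q * fj)
      v <- sum(q * fj * fj) - e1 * e1
      a <- pbar[j] - e1
      h <- max(v, 1e-12)
      u <- lambda[j] + a / h
      u_star <- sign(u) * max(abs(u) - beta[j] / h, 0)
      delta <- u_star - lambda[j]
      if (abs(delta) < 1e-12) next
      delta <- max(min(delta, 10), -10)  # guard against overflow
      accepted <- FALSE
      for (bt in 1:30) {
        lam_try <- lambda
        lam_try[j] <- lambda[j] + delta
        eta_try <- eta + delta * fj
        obj_try <- reg_obj(lam_try, eta_try)
        if (obj_try >= obj - 1e-12) { accepted <- TRUE; break }
        delta <- delta / 2
      }
      if (accepted && obj_try > obj) {
        trace[[length(trace) + 1L]] <-
          c(j = j, gain = obj_try - obj)
        lambda[j] <- lambda[j] + delta
        eta <- eta_try
        obj <- obj_try
      }
    }
    if (obj - obj_cycle_start < tol) { converged <- TRUE; break }
  }

  # fitted distribution over background
  logZ <- log_sum_exp(eta)
  q <- exp(eta - logZ)
  entropy <- -sum(ifelse(q > 0, q * log(q), 0))

  # credit each accepted step's gain increment to the feature's covariate(s)
  contrib <- stats::setNames(numeric(length(covs)), covs)
  if (length(trace)) {
    tr <- do.call(rbind, trace)
    for (i in seq_len(nrow(tr))) {
      j <- tr[i, "j"]
      g <- tr[i, "gain"]
      c1 <- features$defs$covariate[j]
      c2 <- features$defs$covariate2[j]
      if (!is.na(c2)) {
        contrib[c1] <- contrib[c1] + g / 2
        contrib[c2] <- contrib[c2] + g / 2
      } else {
        contrib[c1] <- contrib[c1] + g
      }
    }
  }

  structure(list(
    features = features, lambda = stats::setNames(lambda,
                                                  features$defs$feature),
    beta = stats::setNames(beta, features$defs$feature),
    pbar = pbar, log_z = logZ, entropy = entropy,
    gain = obj - obj0, reg_objective = obj,
    contrib_gain = contrib,
    n_presence = m, n_background = n,
    presence = pr, background_idx = bg_idx,
    converged = converged, cycles = cycles
  ), class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(
    "<maxent_model> %d features, %d presences, %d background cells\n",
    length(x$lambda), x$n_presence, x$n_background))
  cat(sprintf("  gain %.4f | entropy %.4f | %s after %d cycles\n",
              x$gain, x$entropy,
              if (x$converged) "converged" else "not converged", x$cycles))
  invisible(x)
}

#' Raw and logistic suitability maps
#'
#' The raw output is the fitted Gibbs probability per cell,
#' `q(x) = exp(sum(lambda * f(x))) / Z`, normalized so it sums to 1 over the
#' background. The logistic output is the entropy-calibrated transform
#' `e^H q(x) / (1 + e^H q(x))` with `H` the entropy of `q` over background; it
#' is a strictly increasing function of the raw value with range (0, 1).
#'
#' @param model A fitted [maxent_fit()] model.
#' @param stack The covariate stack to project onto (defaults grid-compatible
#'   with the training stack).
#' @return An object of class `suitability_map`: list with `logistic` and
#'   `raw` [raster_grid()]s and the model entropy.
#' @export
logistic_map <- function(model, stack) {
  stopifnot(inherits(model, "maxent_model"),
            inherits(stack, "covariate_stack"))
  df <- as_tibble(stack)
  covs <- model$features$scaling$covariate
  ok <- df$valid
  raw_v <- rep(NA_real_, nrow(df))
  if (any(ok)) {
    Fm <- feature_matrix(model$features, df[ok, covs, drop = FALSE])
    raw_v[ok] <- exp(as.vector(Fm %*% model$lambda) - model$log_z)
  }
  eH <- exp(model$entropy)
  logi_v <- eH * raw_v / (1 + eH * raw_v)
  raw <- stack$grid
  raw$values <- matrix(raw_v, nrow(raw$values), ncol(raw$values))
  raw$name <- "raw_suitability"
  logi <- stack$grid
  logi$values <- matrix(logi_v, nrow(logi$values), ncol(logi$values))
  logi$name <- "logistic_suitability"
  structure(list(logistic = logi, raw = raw, entropy = model$entropy),
            class = "suitability_map")
}

#' @export
print.suitability_map <- function(x, ...) {
  v <- x$logistic$values[!is.na(x$logistic$values)]
  cat(sprintf("<suitability_map> logistic range [%.3f, %.3f], entropy %.4f\n",
              min(v), max(v), x$entropy))
  invisible(x)
}

#' @export
autoplot.suitability_map <- function(object, ...) {
  autoplot(object$logistic) + ggplot2::labs(fill = "suitability")
}

#' Percent contribution of each covariate
#'
#' Each accepted optimization step's gain increment is credited to the
#' updated feature's source covariate (product features split credit equally
#' between their two covariates). Negative accumulations are floored at zero
#' and the result is normalized to sum to 100. When the model has zero total
#' gain the contributions are all zero and flagged.
#'
#' @param model A fitted [maxent_fit()] model.
#' @return A tibble with `covariate` and `contribution` (percent), sorted
#'   decreasing; attribute `"zero_gain"` flags a gainless model.
#' @export
percent_contribution <- function(model) {
  stopifnot(inherits(model, "maxent_model"))
  g <- pmax(model$contrib_gain, 0)
  zero <- sum(g) <= 0
  pct <- if (zero) g * 0 else 100 * g / sum(g)
  out <- tibble::tibble(covariate = names(pct),
                        contribution = as.numeric(pct)) |>
    dplyr::arrange(dplyr::desc(.data$contribution))
  attr(out, "zero_gain") <- zero
  if (zero) warning("model has zero training gain; contributions undefined",
                    call. = FALSE)
  out
}

#' Rank-based AUC of presence vs background scores
#'
#' The Mann-Whitney statistic: the probability that a randomly chosen
#' presence cell scores above a randomly chosen background cell, with ties
#' counted one half.
#'
#' @param presence_scores,background_scores Numeric suitability scores.
#' @return AUC in \[0, 1\]; attribute `"degenerate"` is `TRUE` when every
#'   score is identical (AUC reported as 0.5).
#' @export
auc_roc <- function(presence_scores, background_scores) {
  p <- presence_scores[!is.na(presence_scores)]
  b <- background_scores[!is.na(background_scores)]
  if (!length(p) || !length(b)) {
    stop("need at least one presence and one background score",
         call. = FALSE)
  }
  if (length(unique(c(p, b))) == 1L) {
    out <- 0.5
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  r <- rank(c(p, b))
  auc <- (sum(r[seq_along(p)]) - length(p) * (length(p) + 1) / 2) /
    (length(p) * length(b))
  attr(auc, "degenerate") <- FALSE
  auc
}

#' Training AUC of a fitted model on its own presence/background cells
#'
#' @param model A fitted [maxent_fit()] model.
#' @param map A [logistic_map()] of the same stack.
#' @return AUC in \[0, 1\].
#' @export
model_auc <- function(model, map) {
  nr <- nrow(map$logistic$values)
  p_idx <- model$presence$row + (model$presence$col - 1L) * nr
  p <- map$logistic$values[p_idx]
  b <- map$logistic$values[model$background_idx]
  auc_roc(p, b)
}

#' @export
tidy.maxent_model <- function(x, ...) {
  d <- x$features$defs
  tibble::tibble(
    term = d$feature, class = d$class, covariate = d$covariate,
    knot = d$knot, estimate = as.numeric(x$lambda),
    penalty = as.numeric(x$beta)
  )
}

#' @export
glance.maxent_model <- function(x, ...) {
  tibble::tibble(
    n_presence = x$n_presence, n_background = x$n_background,
    n_features = length(x$lambda),
    n_active = sum(x$lambda != 0),
    gain = x$gain, entropy = x$entropy,
    converged = x$converged, cycles = x$cycles
  )
}
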