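ramp_stack <- function(nr = 15, nc = 15) {
  m <- matrix(rep(seq(0, 1, length.out = nc), each = nr), nr, nc)
  make_stack(grad = m)
}

test_that("feature sets enumerate as documented and stay in [0, 1]", {
  st <- ramp_stack()
  expect_equal(nrow(build_features(st, classes = "linear")$defs), 1L)

  st2 <- make_stack(a = matrix(runif(100), 10, 10),
                    b = matrix(runif(100), 10, 10))
  expect_equal(nrow(build_features(st2,
                                   classes = c("linear", "quadratic"))$defs),
               4L)

  fs <- build_features(st, classes = "hinge", hinge_knots = 5L)
  expect_equal(nrow(fs$defs), 10L)
  fm <- feature_matrix(fs, as_tibble(st)["grad"])
  expect_true(all(fm >= 0 & fm <= 1))

  expect_warning(
    fs2 <- build_features(make_stack(flat = matrix(2, 10, 10),
                                     a = matrix(runif(100), 10, 10))),
    "constant"
  )
  expect_false("flat" %in% fs2$scaling$covariate)
})

test_that("the fitted background distribution is normalized", {
  set.seed(9)
  st <- ramp_stack()
  pres <- tibble::tibble(row = sample(15, 20, TRUE),
                         col = sample(10:15, 20, TRUE))
  model <- maxent_fit(st, pres, beta_multiplier = 1)
  map <- logistic_map(model, st)
  q <- map$raw$values[model$background_idx]
  expect_lt(abs(sum(q) - 1), 1e-9)
})

test_that("infinite regularization drives all weights to zero (uniform q)", {
  st <- ramp_stack()
  pres <- tibble::tibble(row = c(1, 5, 9), col = c(12, 13, 14))
  model <- maxent_fit(st, pres, beta_multiplier = 1e9)
  expect_true(all(model$lambda == 0))
  map <- logistic_map(model, st)
  expect_true(all(abs(map$logistic$values - 0.5) < 1e-12))
  expect_equal(model$entropy, log(model$n_background), tolerance = 1e-12)
})

test_that("a single binary feature recovers the closed-form weight", {
  # covariate is 0/1; with beta = 0 the optimum matches the one-moment
  # maximum-entropy solution lambda = ln(pbar(1-bbar)/(bbar(1-pbar)))
  nr <- 10; nc <- 10
  m <- matrix(0, nr, nc)
  m[, 6:10] <- 1                      # bbar = 0.5
  st <- make_stack(bin = m)
  ones <- which(m == 1, arr.ind = TRUE)
  zeros <- which(m == 0, arr.ind = TRUE)
  pres <- rbind(ones[1:15, ], zeros[1:5, ])   # pbar = 0.75
  model <- maxent_fit(st, tibble::tibble(row = pres[, 1], col = pres[, 2]),
                      features = build_features(st, classes = "linear"),
                      beta_multiplier = 0, tol = 1e-12)
  pbar <- 0.75; bbar <- 0.5
  lam_star <- log(pbar * (1 - bbar) / (bbar * (1 - pbar)))
  expect_equal(unname(model$lambda), lam_star, tolerance = 1e-4)
  # fitted mass on feature-1 cells equals the presence mean
  map <- logistic_map(model, st)
  mass1 <- sum(map$raw$values[m == 1])
  expect_equal(mass1, pbar, tolerance = 1e-6)
})

test_that("coordinate ascent matches a generic convex optimizer's gain", {
  set.seed(123)
  for (rep in 1:3) {
    nr <- 12; nc <- 12
    st <- make_stack(a = matrix(runif(nr * nc), nr, nc),
                     b = matrix(runif(nr * nc), nr, nc))
    fs <- build_features(st, classes = c("linear", "quadratic"))
    pres <- tibble::tibble(row = sample(nr, 25, TRUE),
                           col = sample(nc, 25, TRUE))
    model <- maxent_fit(st, pres, features = fs, beta_multiplier = 0,
                        tol = 1e-10, max_cycles = 2000)

    df <- as_tibble(st)
    Fb <- feature_matrix(fs, df[df$valid, fs$scaling$covariate])
    idx <- pres$row + (pres$col - 1L) * nr
    Fp <- feature_matrix(fs, df[idx, fs$scaling$covariate])
    pbar <- colMeans(Fp)
    nll <- function(lam) {
      eta <- as.vector(Fb %*% lam)
      mx <- max(eta)
      -(sum(pbar * lam) - (mx + log(sum(exp(eta - mx)))))
    }
    grad <- function(lam) {
      eta <- as.vector(Fb %*% lam)
      q <- exp(eta - max(eta)); q <- q / sum(q)
      -(pbar - as.vector(t(Fb) %*% q))
    }
    opt <- optim(rep(0, ncol(Fb)), nll, grad, method = "BFGS",
                 control = list(maxit = 2000, reltol = 1e-14))
    gain_oracle <- -opt$value + log(nrow(Fb))
    expect_lt(abs(model$gain - gain_oracle), 1e-4)
  }
})

test_that("the logistic transform is the entropy-calibrated raw output", {
  # hand-built model with q = (0.5, 0.3, 0.2) on a 1x3 grid
  zb <- log(1.5) / log(2.5)
  st <- make_stack(x = matrix(c(1, zb, 0), 1, 3))
  fs <- build_features(st, classes = "linear")
  lam <- log(2.5)
  eta <- lam * c(1, zb, 0)
  q <- exp(eta) / sum(exp(eta))
  expect_equal(q, c(0.5, 0.3, 0.2), tolerance = 1e-12)
  H <- -sum(q * log(q))
  model <- structure(list(
    features = fs, lambda = c(lin_x = lam), log_z = log(sum(exp(eta))),
    entropy = H, presence = tibble::tibble(row = 1L, col = 1L),
    background_idx = 1:3
  ), class = "maxent_model")
  map <- logistic_map(model, st)
  expect_equal(H, 1.0297, tolerance = 1e-4)
  expect_equal(map$logistic$values[1, 1], 0.58334, tolerance = 1e-4)
  # strictly increasing in raw output
  ord_raw <- order(map$raw$values[1, ])
  expect_equal(order(map$logistic$values[1, ]), ord_raw)
})

test_that("AUC equals brute-force pair counting and handles edge cases", {
  expect_equal(as.numeric(auc_roc(c(0.9, 0.7), c(0.8, 0.6, 0.1))), 5 / 6)
  expect_equal(as.numeric(auc_roc(c(0.9, 0.8), c(0.2, 0.1))), 1)
  d <- auc_roc(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(as.numeric(d), 0.5)
  expect_true(attr(d, "degenerate"))
  set.seed(77)
  for (i in 1:25) {
    p <- sample(0:5, sample(1:6, 1), replace = TRUE) / 5
    b <- sample(0:5, sample(1:8, 1), replace = TRUE) / 5
    expect_equal(as.numeric(auc_roc(p, b)), brute_auc(p, b))
  }
  expect_error(auc_roc(numeric(), 1), "at least one")
})

test_that("gain-based contributions find the planted informative covariate", {
  hits <- 0L
  for (s in 1:10) {
    set.seed(s)
    nr <- 20; nc <- 20
    a <- matrix(rep(seq(0, 1, length.out = nc), each = nr), nr, nc)
    b <- matrix(runif(nr * nc), nr, nc)
    st <- make_stack(a = a, b = b)
    # presence sampled with probability proportional to exp(3 * a)
    w <- exp(3 * as.vector(a))
    idx <- sample(nr * nc, 80, replace = TRUE, prob = w)
    pres <- tibble::tibble(row = (idx - 1L) %% nr + 1L,
                           col = (idx - 1L) %/% nr + 1L)
    model <- maxent_fit(st, pres,
                        features = build_features(st,
                                                  classes = c("linear",
                                                              "quadratic")))
    pc <- percent_contribution(model)
    expect_lt(abs(sum(pc$contribution) - 100), 1e-9)
    if (pc$contribution[pc$covariate == "a"] > 80) hits <- hits + 1L
  }
  expect_gte(hits, 9L)

  # single covariate models put all credit on it
  st1 <- ramp_stack()
  m1 <- maxent_fit(st1, tibble::tibble(row = c(2, 3), col = c(14, 15)),
                   features = build_features(st1, classes = "linear"))
  pc1 <- percent_contribution(m1)
  expect_equal(pc1$contribution, 100)
})

test_that("a planted exponential response is recovered within 15%", {
  errs <- vapply(1:20, function(s) {
    set.seed(s)
    nr <- 30; nc <- 30
    a <- matrix(rep(seq(0, 1, length.out = nc), each = nr), nr, nc)
    st <- make_stack(a = a)
    true_a <- 2
    w <- exp(true_a * as.vector(a))
    idx <- sample(nr * nc, 200, replace = TRUE, prob = w)
    pres <- tibble::tibble(row = (idx - 1L) %% nr + 1L,
                           col = (idx - 1L) %/% nr + 1L)
    model <- maxent_fit(st, pres,
                        features = build_features(st, classes = "linear"),
                        beta_multiplier = 0, tol = 1e-10)
    abs(unname(model$lambda) - true_a) / true_a
  }, numeric(1))
  expect_lt(median(errs), 0.15)
})

test_that("adding a duplicate covariate never decreases training gain", {
  set.seed(14)
  a <- matrix(runif(144), 12, 12)
  pres <- tibble::tibble(row = sample(12, 20, TRUE),
                         col = sample(12, 20, TRUE))
  fit1 <- maxent_fit(make_stack(a = a),
                     pres, beta_multiplier = 0, tol = 1e-10,
                     features = build_features(make_stack(a = a),
                                               classes = "linear"))
  st2 <- make_stack(a = a, a2 = a)
  fit2 <- maxent_fit(st2, pres, beta_multiplier = 0, tol = 1e-10,
                     features = build_features(st2, classes = "linear"))
  expect_gte(fit2$gain, fit1$gain - 1e-8)
})

test_that("degenerate presence inputs are rejected with locations", {
  st <- ramp_stack()
  expect_error(maxent_fit(st, tibble::tibble(row = integer(),
                                             col = integer())),
               "at least one presence")
  st$layers$grad$values[3, 4] <- NA
  expect_error(maxent_fit(st, tibble::tibble(row = 3L, col = 4L)),
               "\\(3, 4\\)")
})
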