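make_feature_rows <- function(cell_id, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(cell_id = cell_id, frame = seq_len(n), axis = "orthogonal",
             accel = rnorm(n), x1_vel = rnorm(n), x2_erk_grad = rnorm(n),
             x3_rho_grad = rnorm(n), x4_d2v_dx2 = rnorm(n),
             x5_d2v_dy2 = rnorm(n), rho = 1, stringsAsFactors = FALSE)
}

test_that("lagged design has the documented shape and never mixes cells", {
  tab <- make_feature_rows("a", 5L, seed = 1)
  d <- build_design(tab, lag_spec(L = 2L))
  expect_identical(dim(d$X), c(4L, 10L))
  expect_identical(d$index$frame, 2:5)

  d20 <- build_design(make_feature_rows("a", 20L, seed = 2), lag_spec(L = 20L))
  expect_identical(nrow(d20$X), 1L)

  two <- rbind(make_feature_rows("a", 8L, seed = 3), make_feature_rows("b", 12L))
  d2 <- build_design(two, lag_spec(L = 5L))
  expect_identical(nrow(d2$X), (8L - 4L) + (12L - 4L))
  expect_identical(as.integer(table(d2$index$cell_id)[c("a", "b")]), c(4L, 8L))

  # lag block layout: row for frame t holds x(t), x(t-1), ..., x(t-L+1)
  tab_a <- make_feature_rows("a", 6L, seed = 4)
  da <- build_design(tab_a, lag_spec(L = 3L))
  expect_equal(da$X[1L, 3:5], tab_a$x2_erk_grad[3:1])
  expect_equal(da$X[2L, 6:8], tab_a$x3_rho_grad[4:2])
  expect_equal(da$X[1L, 1:2], c(1, tab_a$x1_vel[3L]))

  gap <- make_feature_rows("gappy", 10L, seed = 5)
  gap <- gap[gap$frame != 4L, ]
  expect_error(build_design(gap, lag_spec(L = 3L)), "gappy")
})

test_that("ridge solution matches the closed-form oracle on random systems", {
  set.seed(31)
  L <- 3L
  p <- 2L + 4L * L
  for (rep in 1:10) {
    X <- cbind(1, matrix(rnorm(50 * (p - 1L)), 50))
    y <- rnorm(50)
    lam <- 10^runif(1, -3, 3)
    theta <- ridge_solve(X, y, lam)
    Ipen <- diag(c(0, rep(1, p - 1L)))
    oracle <- qr.solve(crossprod(X) + lam * Ipen, t(X) %*% y)
    expect_equal(theta, drop(oracle), tolerance = 1e-8)
  }
})

test_that("ridge limits: ordinary least squares at lambda -> 0, shrinkage at large lambda", {
  set.seed(32)
  X <- cbind(1, matrix(rnorm(60 * 7), 60))
  y <- rnorm(60)
  theta0 <- ridge_solve(X, y, 1e-10)
  ols <- unname(coef(lm(y ~ X[, -1])))
  expect_equal(theta0, ols, tolerance = 1e-6)

  theta_inf <- ridge_solve(X, y, 1e12)
  expect_lt(max(abs(theta_inf[-1L])), 1e-9)
  expect_equal(theta_inf[1L], mean(y), tolerance = 1e-6)
})

test_that("penalized-coefficient norm is non-increasing in lambda", {
  set.seed(33)
  X <- cbind(1, matrix(rnorm(80 * 9), 80))
  y <- X %*% c(0.5, rnorm(9)) + rnorm(80)
  norms <- vapply(10^seq(-4, 6, by = 0.5), function(l)
    sqrt(sum(ridge_solve(X, y, l)[-1L]^2)), numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("with L = 1 the fit reduces to plain multivariate linear regression", {
  set.seed(34)
  tab <- make_feature_rows("a", 120L)
  d <- build_design(tab, lag_spec(L = 1L))
  rf <- ridge_fit(d, 1e-10)
  ref <- lm(accel ~ x1_vel + x2_erk_grad + x3_rho_grad + x4_d2v_dx2 +
              x5_d2v_dy2, data = tab)
  b <- unname(coef(ref))
  expect_equal(rf$w0, b[1L], tolerance = 1e-6)
  expect_equal(rf$w1, -b[2L], tolerance = 1e-6)  # friction sign convention
  expect_equal(unname(unlist(rf$kernels)), b[3:6], tolerance = 1e-6)
})

test_that("standardized fitting returns coefficients in raw units", {
  gen <- generate_linear_response_dataset(
    synthetic_spec(n_cells = 15L, n_frames = 120L, noise_frac = 0.05, seed = 8))
  d <- build_design(gen$table, gen$rf$lag)
  raw <- ridge_fit(d, 1e-8)
  std <- ridge_fit(d, 1e-8, standardize = TRUE)
  expect_equal(unlist(std$kernels), unlist(raw$kernels), tolerance = 1e-4)
  expect_equal(std$w1, raw$w1, tolerance = 1e-4)
})

test_that("cross-validation prefers minimal shrinkage on noiseless data", {
  gen <- generate_linear_response_dataset(
    synthetic_spec(n_cells = 12L, n_frames = 150L, noise_frac = 0, seed = 9))
  d <- build_design(gen$table, gen$rf$lag)
  cv <- cv_lambda(d, ridge_config(seed = 1))
  expect_lte(cv$lambda, 1e-4)
  # CV error is non-decreasing beyond the minimum on the broad grid
  broad <- cv$curve[cv$curve$stage == 1L, ]
  after_min <- broad$cv_error[which.min(broad$cv_error):nrow(broad)]
  expect_true(all(diff(after_min) >= -1e-12))
})

test_that("cross-validation selects strong shrinkage for a pure-noise target", {
  set.seed(35)
  lambdas <- vapply(1:20, function(i) {
    tab <- make_feature_rows("a", 60L)
    d <- build_design(tab, lag_spec(L = 2L))
    cv_lambda(d, ridge_config(seed = i))$lambda
  }, numeric(1))
  expect_gte(median(log10(lambdas)), 1)
})

test_that("cell-wise folds partition the cells", {
  tab <- do.call(rbind, lapply(sprintf("c%03d", 1:100), make_feature_rows,
                               n = 12L))
  set.seed(36)
  tab$accel <- rnorm(nrow(tab))
  d <- build_design(tab, lag_spec(L = 3L))
  cv <- cv_lambda(d, ridge_config(grouping = "cell", seed = 4))
  folds_per_cell <- tapply(cv$folds, d$index$cell_id, function(f)
    length(unique(f)))
  expect_true(all(folds_per_cell == 1L))
  expect_identical(sort(unique(cv$folds)), 1:5)
})

test_that("grouped-fold refits are identical for duplicated cells and stable on synthetic data", {
  base <- make_feature_rows("tpl", 40L, seed = 37)
  dup <- do.call(rbind, lapply(sprintf("c%02d", 1:10), function(id) {
    b <- base
    b$cell_id <- id
    b
  }))
  st <- grouped_cv_stability(dup, lag_spec(L = 4L),
                             ridge_config(lambda = 1, grouping = "cell",
                                          folds = 5L, seed = 2))
  expect_equal(min(st$similarity), 1, tolerance = 1e-9)

  expect_error(grouped_cv_stability(base, lag_spec(L = 4L),
                                    ridge_config(lambda = 1, folds = 5L,
                                                 grouping = "cell")),
               "at least 5 cells")
})

test_that("fold kernels agree closely at the study scale", {
  fx <- recovery_fixture()
  st <- grouped_cv_stability(fx$gen$table, fx$gen$rf$lag,
                             ridge_config(lambda = 10, grouping = "cell",
                                          folds = 5L, seed = 3))
  expect_gt(min(st$similarity), 0.9)
})

test_that("prediction reproduces noiseless targets and is linear in the features", {
  gen <- generate_linear_response_dataset(
    synthetic_spec(n_cells = 10L, n_frames = 120L, noise_frac = 0, seed = 10))
  d <- build_design(gen$table, gen$rf$lag)
  rf <- ridge_fit(d, 1e-10)
  pred <- predict_acceleration(rf, gen$table)
  expect_equal(pred$predicted, pred$observed, tolerance = 1e-6)

  bias_only <- rf_from_vector(c(0.7, rep(0, 1 + 4 * 20)), 20L)
  pb <- predict_acceleration(bias_only, gen$table)
  expect_equal(pb$predicted, rep(0.7, nrow(pb)), tolerance = 1e-12)

  # linearity over feature tables sharing an index
  A <- gen$table
  B <- gen$table
  set.seed(38)
  num <- c("accel", "x1_vel", "x2_erk_grad", "x3_rho_grad", "x4_d2v_dx2",
           "x5_d2v_dy2")
  B[num] <- lapply(B[num], function(x) x + rnorm(length(x)))
  combo <- A
  combo[num] <- 2 * A[num] - 3 * B[num]
  rf_nb <- rf
  rf_nb$w0 <- 0
  pc <- predict_acceleration(rf_nb, combo)$predicted
  pa <- predict_acceleration(rf_nb, A)$predicted
  pb2 <- predict_acceleration(rf_nb, B)$predicted
  expect_equal(pc, 2 * pa - 3 * pb2, tolerance = 1e-8)
})

test_that("prediction matches by-hand dot products on a tiny example", {
  L <- 2L
  tab <- data.frame(cell_id = "z", frame = 1:3, axis = "orthogonal",
                    accel = c(0, 0, 0), x1_vel = c(1, 2, 3),
                    x2_erk_grad = c(0.1, 0.2, 0.3),
                    x3_rho_grad = c(1, 0, -1), x4_d2v_dx2 = c(0, 1, 0),
                    x5_d2v_dy2 = c(-1, -1, -1), rho = 1)
  rf <- rf_from_vector(c(0.5, 0.4, 1, 2, 3, 4, 5, 6, 7, 8), L)
  # theta = [w0, -w1, kernels...]; row t=2: [1, 2, 0.2, 0.1, 0, 1, 1, 0, -1, -1]
  manual <- c(0.5 - 0.4 * 2 + 1 * 0.2 + 2 * 0.1 + 3 * 0 + 4 * 1 + 5 * 1 +
                6 * 0 + 7 * (-1) + 8 * (-1),
              0.5 - 0.4 * 3 + 1 * 0.3 + 2 * 0.2 + 3 * (-1) + 4 * 0 + 5 * 0 +
                6 * 1 + 7 * (-1) + 8 * (-1))
  pred <- predict_acceleration(rf, tab)
  expect_equal(pred$predicted, manual, tolerance = 1e-12)
})

test_that("axis mismatch between model and table is rejected", {
  gen <- generate_linear_response_dataset(
    synthetic_spec(rf = default_true_rf(L = 5L), n_cells = 3L, n_frames = 30L,
                   noise_frac = 0, seed = 11))
  rf_par <- default_true_rf(L = 5L, axis = "parallel")
  expect_error(predict_acceleration(rf_par, gen$table), "axis mismatch")
})

test_that("cosine similarity has its closed-form values and flags zero vectors", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 0), c(1, 1)), 1 / sqrt(2),
               tolerance = 1e-12)
  expect_warning(out <- cosine_similarity(c(0, 0), c(1, 1)), "zero")
  expect_true(is.na(out))
})

test_that("response functions round-trip losslessly through the model file", {
  set.seed(39)
  rf <- random_rf(L = 20L, axis = "parallel")
  path <- withr::local_tempfile(fileext = ".txt")
  write_response_function(rf, path)
  back <- read_response_function(path)
  expect_identical(back$axis, "parallel")
  expect_identical(back$lag$L, 20L)
  expect_identical(flatten_rf(back, TRUE, TRUE), flatten_rf(rf, TRUE, TRUE))
  expect_identical(back$lag$frame_interval, rf$lag$frame_interval)
})

test_that("continuum coefficient mapping carries the derived signs", {
  cm <- continuum_coefficients(mu0 = 10, beta = 2.5, alpha = 1.5, k = 2,
                               R0 = 0.5, eta = 0.3, rho_ref = 0.005,
                               erk_ref = 0.2)
  expect_equal(cm$c_vel, -10 * (1 - 2.5 * 0.2))
  expect_equal(cm$c_erk, -2 * 1.5 * 2 * 0.5 / 0.005)
  expect_equal(cm$c_rho, -2 / 0.005^3)
  expect_equal(cm$c_visc_x, 0.3 / 0.005^2)
  expect_identical(cm$c_visc_x, cm$c_visc_y)
  expect_error(continuum_coefficients(10, 2.5, 1.5, 2, 0.5, 0, rho_ref = 0),
               "rho_ref")
})
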