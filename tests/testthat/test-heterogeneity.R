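two_population_tables <- function(n_per_group = 12L, n_frames = 150L,
                                  noise_frac = 0.1, seed = 50L) {
  rf_a <- default_true_rf(L = 10L)
  rf_b <- rf_a
  rf_b$kernels$erk_grad <- -rf_b$kernels$erk_grad
  gen_a <- generate_linear_response_dataset(
    synthetic_spec(rf = rf_a, n_cells = n_per_group, n_frames = n_frames,
                   noise_frac = noise_frac, seed = seed))
  gen_b <- generate_linear_response_dataset(
    synthetic_spec(rf = rf_b, n_cells = n_per_group, n_frames = n_frames,
                   noise_frac = noise_frac, seed = seed + 1L))
  gen_b$table$cell_id <- sub("^cell_", "bcell_", gen_b$table$cell_id)
  tab <- rbind(gen_a$table, gen_b$table)
  attr(tab, "axis") <- "orthogonal"
  class(tab) <- c("feature_table", "data.frame")
  list(table = tab, rf_a = rf_a, rf_b = rf_b,
       ids_a = unique(gen_a$table$cell_id),
       ids_b = unique(sub("^cell_", "bcell_", gen_b$table$cell_id)))
}

test_that("per-cell fits of a homogeneous population are mutually similar", {
  gen <- generate_linear_response_dataset(
    synthetic_spec(rf = default_true_rf(L = 10L), n_cells = 15L,
                   n_frames = 150L, noise_frac = 0.05, seed = 51))
  rf_set <- fit_per_cell(gen$table, gen$rf$lag, lambda = 2)
  S <- similarity_matrix(rf_set)
  expect_gt(min(S[upper.tri(S)]), 0.95)
})

test_that("planted subpopulations with opposite ERK kernels show block structure", {
  pop <- two_population_tables()
  rf_set <- fit_per_cell(pop$table, pop$rf_a$lag, lambda = 2)
  S <- similarity_matrix(rf_set)
  expect_gt(block_contrast(S, pop$ids_a, pop$ids_b), 0.5)
})

test_that("cells without a full lag history are excluded with a reason", {
  gen <- generate_linear_response_dataset(
    synthetic_spec(rf = default_true_rf(L = 10L), n_cells = 4L,
                   n_frames = 60L, noise_frac = 0, seed = 52))
  short <- gen$table[!(gen$table$cell_id == "cell_0001" & gen$table$frame > 9L), ]
  rf_set <- fit_per_cell(short, gen$rf$lag, lambda = 1)
  expect_false("cell_0001" %in% names(rf_set$rfs))
  expect_match(rf_set$excluded[["cell_0001"]], "9 frames")
  expect_length(rf_set$rfs, 3L)
})

test_that("ranking scores noiseless cells perfectly and demotes degenerate ones", {
  gen <- generate_linear_response_dataset(
    synthetic_spec(rf = default_true_rf(L = 8L), n_cells = 6L, n_frames = 80L,
                   noise_frac = 0, seed = 53))
  rk <- rank_cells(gen$rf, gen$table)
  expect_equal(rk$score, rep(1, 6L), tolerance = 1e-9)
  expect_identical(rk$cell_id, sort(rk$cell_id))  # ties break by id

  # a cell with constant observed acceleration has no defined correlation
  tab <- gen$table
  tab$accel[tab$cell_id == "cell_0003"] <- 0.25
  rk2 <- rank_cells(gen$rf, tab)
  expect_identical(rk2$cell_id[6L], "cell_0003")
  expect_true(is.na(rk2$score[6L]))
})

test_that("a shuffled-target cell ranks last with high probability", {
  last_hits <- vapply(1:5, function(s) {
    gen <- generate_linear_response_dataset(
      synthetic_spec(rf = default_true_rf(L = 8L), n_cells = 8L,
                     n_frames = 100L, noise_frac = 0.05, seed = 60L + s))
    tab <- gen$table
    rows <- tab$cell_id == "cell_0005"
    set.seed(s)
    tab$accel[rows] <- sample(tab$accel[rows])
    rank_cells(gen$rf, tab)$cell_id[8L] == "cell_0005"
  }, logical(1))
  expect_gte(sum(last_hits), 4L)
})

test_that("similarity matrices are symmetric, unit-diagonal, scale-invariant and match a loop oracle", {
  set.seed(54)
  rfs <- setNames(lapply(1:10, function(i) random_rf(L = 5L)),
                  sprintf("r%02d", 1:10))
  rf_set <- structure(list(rfs = rfs, excluded = character(0), lambda = 1),
                      class = "cell_rf_set")
  S <- similarity_matrix(rf_set)
  expect_equal(S, t(S))
  expect_equal(unname(diag(S)), rep(1, 10L))

  oracle <- matrix(NA_real_, 10, 10)
  for (i in 1:10) for (j in 1:10)
    oracle[i, j] <- cosine_similarity(flatten_rf(rfs[[i]]), flatten_rf(rfs[[j]]))
  expect_equal(unname(S), oracle, tolerance = 1e-12)

  scaled <- rf_set
  scaled$rfs <- lapply(rfs, function(r) {
    r$w0 <- 3 * r$w0
    r$w1 <- 3 * r$w1
    r$kernels <- lapply(r$kernels, `*`, 3)
    r
  })
  expect_equal(similarity_matrix(scaled), S, tolerance = 1e-12)

  # sign flip produces -1 against the original
  pair <- structure(list(rfs = list(a = rfs[[1L]], b = scaled$rfs[[1L]],
                                    c = local({
                                      r <- rfs[[1L]]
                                      r$w1 <- -r$w1
                                      r$kernels <- lapply(r$kernels, `*`, -1)
                                      r
                                    }))),
                    class = "cell_rf_set")
  Sp <- similarity_matrix(pair)
  expect_equal(Sp["a", "b"], 1, tolerance = 1e-12)
  expect_equal(Sp["a", "c"], -1, tolerance = 1e-12)
})

test_that("PCA of response functions captures planted low-dimensional structure", {
  L <- 5L
  p <- 1L + 4L * L
  set.seed(55)
  u <- rnorm(p)
  line_rfs <- setNames(lapply(1:8, function(i)
    rf_from_vector(c(0, (i - 4.5) * u), L)), sprintf("l%d", 1:8))
  line_set <- structure(list(rfs = line_rfs), class = "cell_rf_set")
  pca_line <- pca_response_functions(line_set)
  expect_equal(pca_line$explained[1L], 1, tolerance = 1e-9)

  v <- rnorm(p)
  v <- v - u * sum(u * v) / sum(u^2)  # orthogonalize
  u <- u / sqrt(sum(u^2))
  v <- v / sqrt(sum(v^2))
  set.seed(56)
  n_pts <- 4000L
  two_rfs <- setNames(lapply(seq_len(n_pts), function(i)
    rf_from_vector(c(0, rnorm(1) * u + rnorm(1) * v), L)),
    sprintf("t%04d", seq_len(n_pts)))
  two_set <- structure(list(rfs = two_rfs), class = "cell_rf_set")
  pca_two <- pca_response_functions(two_set)
  # two equal-power directions: ~50% each, within 5 percentage points
  expect_lt(abs(pca_two$explained[1L] - 0.5), 0.05)
  expect_lt(abs(pca_two$explained[2L] - 0.5), 0.05)
  expect_lt(sum(pca_two$explained[-(1:2)]), 1e-9)
  expect_equal(sum(pca_two$explained), 1, tolerance = 1e-12)

  # scores are centred and reconstruct the centred vectors exactly
  expect_lt(max(abs(colMeans(pca_two$scores))), 1e-10)
  V <- t(vapply(two_rfs, flatten_rf, numeric(p)))
  recon <- pca_two$scores %*% t(pca_two$rotation)
  expect_equal(unname(recon + rep(pca_two$center, each = n_pts)), unname(V),
               tolerance = 1e-9)
})

test_that("subgroup means separate planted strong and weak responders", {
  all_same <- structure(list(rfs = setNames(
    lapply(1:6, function(i) default_true_rf(L = 6L)), sprintf("s%d", 1:6))),
    class = "cell_rf_set")
  rank_same <- data.frame(cell_id = sprintf("s%d", 1:6), score = 1,
                          rank = 1:6)
  sg <- subgroup_mean_rf(all_same, rank_same, n_best = 2L, n_worst = 2L)
  expect_equal(flatten_rf(sg$best), flatten_rf(default_true_rf(L = 6L)))
  expect_equal(flatten_rf(sg$worst), flatten_rf(default_true_rf(L = 6L)))
  expect_error(subgroup_mean_rf(all_same, rank_same, 4L, 4L), "exceeds")

  # bottom-ranked cells carry flat, low-amplitude kernels
  strong <- default_true_rf(L = 6L)
  weak <- strong
  weak$kernels <- lapply(weak$kernels, `*`, 0.1)
  rfs <- c(setNames(lapply(1:5, function(i) strong), sprintf("top%d", 1:5)),
           setNames(lapply(1:5, function(i) weak), sprintf("wk%d", 1:5)))
  rf_set <- structure(list(rfs = rfs), class = "cell_rf_set")
  ranking <- data.frame(cell_id = names(rfs), score = seq(1, 0.1, length.out = 10),
                        rank = 1:10)
  sg2 <- subgroup_mean_rf(rf_set, ranking, 5L, 5L)
  expect_lt(max(abs(unlist(sg2$worst$kernels))),
            max(abs(unlist(sg2$best$kernels))))
})
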