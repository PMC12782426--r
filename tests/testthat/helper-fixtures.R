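# Fixture builders shared across test files. Everything is generated in code;
# the larger recovery dataset is built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

# The kernel-recovery study conditions: 300 cells x 400 frames, L = 20,
# acceleration noise at 10% of the noiseless target SD.
recovery_fixture <- function() {
  if (is.null(.fixture_env$recovery)) {
    spec <- synthetic_spec(n_cells = 300L, n_frames = 400L,
                           noise_frac = 0.1, seed = 20260920L)
    gen <- generate_linear_response_dataset(spec)
    design <- build_design(gen$table, gen$rf$lag)
    .fixture_env$recovery <- list(gen = gen, design = design)
  }
  .fixture_env$recovery
}

# A simple straight track: positions follow the supplied functions of the
# frame index.
make_track <- function(cell_id, n, x = function(t) t, y = function(t) 0 * t,
                       erk = function(t) 1 + 0 * t, first_frame = 1L) {
  t <- seq_len(n)
  data.frame(cell_id = cell_id, frame = first_frame + t - 1L,
             x_px = x(t), y_px = y(t), erk = erk(t),
             stringsAsFactors = FALSE)
}

# A drifting epithelial sheet on a regular grid with a configurable ERK field;
# all cells share one velocity, so the velocity field is spatially constant.
make_sheet_tracks <- function(nx = 7L, ny = 7L, n_frames = 15L, spacing = 5,
                              vel = c(0.2, -0.1),
                              erk_fun = function(x, y, t) 0.01 * x) {
  grid <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    t <- seq_len(n_frames)
    x <- grid$ix[i] * spacing + vel[1L] * (t - 1)
    y <- grid$iy[i] * spacing + vel[2L] * (t - 1)
    data.frame(cell_id = sprintf("c%03d", i), frame = t, x_px = x, y_px = y,
               erk = erk_fun(x, y, t), stringsAsFactors = FALSE)
  })
  as_track_table(do.call(rbind, rows))
}

# Response function with the given flattened coefficients [w0, w1, kernels].
rf_from_vector <- function(theta, L, axis = "orthogonal") {
  ker <- split(theta[-(1:2)], rep(seq_len(4L), each = L))
  names(ker) <- c("erk_grad", "rho_grad", "d2v_dx2", "d2v_dy2")
  response_function(w0 = theta[1L], w1 = theta[2L], kernels = ker,
                    axis = axis, lag = lag_spec(L))
}

random_rf <- function(L = 6L, axis = "orthogonal") {
  rf_from_vector(stats::rnorm(2L + 4L * L), L, axis)
}

kernel_rel_error <- function(fitted, truth) {
  vapply(names(truth$kernels), function(k)
    sqrt(sum((fitted$kernels[[k]] - truth$kernels[[k]])^2)) /
      sqrt(sum(truth$kernels[[k]]^2)),
    numeric(1L))
}

# Mean within-group minus mean between-group cosine similarity for a
# 2-group split of a similarity matrix.
block_contrast <- function(S, ids_a, ids_b) {
  ia <- match(ids_a, colnames(S))
  ib <- match(ids_b, colnames(S))
  off <- function(M) mean(M[upper.tri(M)])
  within_ <- mean(c(off(S[ia, ia]), off(S[ib, ib])))
  between <- mean(S[ia, ib])
  within_ - between
}
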