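#' Ground-truth response function used by the synthetic generator
#'
#' A biphasic, differentiator-like ERK-gradient kernel (positive peak at lag
#' 0, negative undershoot near lag 3-4, back to zero within ~10 frames), a
#' smoother and more sustained density-gradient kernel, and two delayed
#' positive velocity-curvature bumps — the qualitative shapes reported for
#' interior wound-healing cells.
#'
#' @param L Kernel length in lag frames (default 20).
#' @param axis Axis tag for the returned response function.
#' @param frame_interval Minutes per frame.
#' @return A [response_function()].
#' @export
default_true_rf <- function(L = 20L, axis = "orthogonal", frame_interval = 2) {
  tau <- seq_len(L) - 1
  response_function(
    w0 = 0.05, w1 = 0.6,
    kernels = list(
      erk_grad = 1.2 * exp(-tau / 1.2) - 0.55 * exp(-(tau - 3.5)^2 / 8),
      rho_grad = 0.5 * (tau / 2) * exp(1 - tau / 2),
      d2v_dx2 = 0.4 * exp(-(tau - 2)^2 / 4.5),
      d2v_dy2 = 0.35 * exp(-(tau - 2.5)^2 / 8)),
    axis = axis, lag = lag_spec(L, frame_interval))
}

#' Specification of a synthetic linear-response dataset
#'
#' Features are stationary first-order autoregressions (discretized
#' Ornstein-Uhlenbeck processes) per cell and feature; the acceleration
#' target is the exact convolution of the ground-truth response function with
#' the feature histories plus Gaussian noise scaled to a fraction of the
#' noiseless target's standard deviation.
#'
#' @param rf Ground-truth [response_function()].
#' @param n_cells,n_frames Dataset size (defaults mirror the imaging scale:
#'   hundreds of cells, 400 frames at 2 min).
#' @param ar_coef Lag-1 autocorrelation of the feature processes (default
#'   0.85, a correlation time of ~6 frames, comparable to the effective
#'   response window).
#' @param feature_sd Stationary standard deviation of each feature.
#' @param noise_frac Noise SD as a fraction of the noiseless target SD.
#' @param short_track_frac,missing_frac Fractions of cells given planted
#'   defects by [inject_track_defects()].
#' @param seed Seed fixing all randomness.
#' @return A list with class `synthetic_spec`.
#' @export
synthetic_spec <- function(rf = default_true_rf(), n_cells = 300L,
                           n_frames = 400L, ar_coef = 0.85, feature_sd = 1,
                           noise_frac = 0.1, short_track_frac = 0,
                           missing_frac = 0, seed = 1L) {
  stop_if_not_scalar_num(n_cells, "n_cells", positive = TRUE, integer = TRUE)
  stop_if_not_scalar_num(n_frames, "n_frames", positive = TRUE, integer = TRUE)
  if (n_frames <= rf$lag$L) stop("'n_frames' must exceed the kernel length L")
  if (noise_frac < 0) stop("'noise_frac' must be >= 0")
  if (abs(ar_coef) >= 1) stop("'ar_coef' must lie in (-1, 1)")
  for (nm in c("short_track_frac", "missing_frac")) {
    v <- get(nm)
    if (v < 0 || v > 1) stop(sprintf("'%s' must lie in [0, 1]", nm))
  }
  structure(list(rf = rf, n_cells = as.integer(n_cells),
                 n_frames = as.integer(n_frames), ar_coef = ar_coef,
                 feature_sd = feature_sd, noise_frac = noise_frac,
                 short_track_frac = short_track_frac,
                 missing_frac = missing_frac, seed = seed),
            class = "synthetic_spec")
}

# Stationary AR(1) series of length n with lag-1 coefficient phi and
# stationary SD s; initialized from the stationary distribution.
ar1_series <- function(n, phi, s) {
  x0 <- stats::rnorm(1L, sd = s)
  innov_sd <- s * sqrt(1 - phi^2)
  as.numeric(stats::filter(stats::rnorm(n, sd = innov_sd), phi,
                           method = "recursive", init = x0))
}

#' Generate a synthetic feature table with known response function
#'
#' `accel(t) = w0 - w1 x1(t) + sum_i sum_tau w_i(tau) x_i(t - tau) + noise`,
#' with features drawn from smooth autocorrelated processes. The first AR
#' draw per cell is taken from the process's stationary distribution, so the
#' convolution target is exact for every frame with full history; early
#' frames (lacking history) carry the partial-sum convolution and are
#' excluded from any lagged design anyway. Bit-reproducible given the seed.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `table` (a feature table), `rf` (the ground truth) and
#'   `noise_sd` (the realized noise SD in target units).
#' @export
generate_linear_response_dataset <- function(spec) {
  rf <- spec$rf
  L <- rf$lag$L
  n <- spec$n_frames
  theta_kernels <- rf$kernels
  local_seed(spec$seed, {
    feats <- lapply(seq_len(spec$n_cells), function(i)
      vapply(1:5, function(j) ar1_series(n, spec$ar_coef, spec$feature_sd),
             numeric(n)))
    noiseless <- lapply(feats, function(F) {
      conv <- numeric(n)
      for (ki in seq_along(kernel_names)) {
        kern <- theta_kernels[[ki]]
        x <- F[, ki + 1L]
        full <- as.numeric(stats::filter(x, kern, method = "convolution",
                                         sides = 1L))
        head_idx <- seq_len(min(L - 1L, n))
        full[head_idx] <- vapply(head_idx, function(t)
          sum(kern[seq_len(t)] * x[t - seq_len(t) + 1L]), numeric(1L))
        conv <- conv + full
      }
      rf$w0 - rf$w1 * F[, 1L] + conv
    })
    full_rows <- L:n
    noise_sd <- spec$noise_frac *
      stats::sd(unlist(lapply(noiseless, `[`, full_rows)))
    tables <- lapply(seq_len(spec$n_cells), function(i) {
      eps <- if (noise_sd > 0) stats::rnorm(n, sd = noise_sd) else numeric(n)
      data.frame(cell_id = sprintf("cell_%04d", i), frame = seq_len(n),
                 axis = rf$axis, accel = noiseless[[i]] + eps,
                 x1_vel = feats[[i]][, 1L],
                 x2_erk_grad = feats[[i]][, 2L],
                 x3_rho_grad = feats[[i]][, 3L],
                 x4_d2v_dx2 = feats[[i]][, 4L],
                 x5_d2v_dy2 = feats[[i]][, 5L],
                 rho = 1, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, tables)
    class(out) <- c("feature_table", "data.frame")
    attr(out, "axis") <- rf$axis
    attr(out, "frame_interval") <- rf$lag$frame_interval
    list(table = out, rf = rf, noise_sd = noise_sd)
  })
}

#' Plant short tracks and missing values into a track table
#'
#' Used to exercise the trajectory filters with known ground truth: a
#' fraction of cells is truncated below the filter length and a disjoint
#' fraction receives a missing ERK value. The planted cell ids are recorded
#' in the `planted` attribute.
#'
#' @param tracks A track table.
#' @param short_frac Fraction of cells truncated to fewer than `min_frames`.
#' @param missing_frac Fraction of cells given one missing value.
#' @param min_frames Filter threshold the truncation undercuts (default 400).
#' @param seed Seed.
#' @return The modified track table with attribute
#'   `planted = list(short = ids, missing = ids)`.
#' @export
inject_track_defects <- function(tracks, short_frac = 0, missing_frac = 0,
                                 min_frames = 400L, seed = 1L) {
  for (nm in c("short_frac", "missing_frac")) {
    v <- get(nm)
    if (v < 0 || v > 1) stop(sprintf("'%s' must lie in [0, 1]", nm))
  }
  tracks <- as_track_table(tracks)
  ids <- unique(tracks$cell_id)
  local_seed(seed, {
    n_short <- round(short_frac * length(ids))
    n_miss <- round(missing_frac * length(ids))
    short_ids <- sample(ids, n_short)
    miss_ids <- sample(setdiff(ids, short_ids), min(n_miss, length(ids) - n_short))
    keep <- rep(TRUE, nrow(tracks))
    for (cid in short_ids) {
      rows <- which(tracks$cell_id == cid)
      len <- sample(seq(min(50L, min_frames - 1L), min_frames - 1L), 1L)
      keep[rows[-seq_len(min(len, length(rows)))]] <- FALSE
    }
    out <- tracks[keep, , drop = FALSE]
    for (cid in miss_ids) {
      rows <- which(out$cell_id == cid)
      out$erk[sample(rows, 1L)] <- NA_real_
    }
    rownames(out) <- NULL
    class(out) <- c("track_table", "data.frame")
    attr(out, "planted") <- list(short = sort(short_ids),
                                 missing = sort(miss_ids))
    out
  })
}
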