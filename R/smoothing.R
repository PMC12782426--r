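#' Smoothing and local-fit configuration
#'
#' Bundles the numerical parameters of the feature-extraction stage.
#'
#' @param sg_window Savitzky-Golay window in frames; odd (default 11).
#' @param sg_order Polynomial order of the Savitzky-Golay fit (default 2).
#' @param fit_radius_erk Neighborhood radius in pixels for the local quadratic
#'   fit of scalar fields (ERK, density); default 10.
#' @param fit_radius_vel Neighborhood radius in pixels for the local quadratic
#'   fit of the velocity field; default 10.
#' @param kde_sigma Bandwidth (pixels) of the Gaussian kernel-density estimate
#'   of the cell-density field; default 25.
#' @param image_sigma Gaussian pre-smoothing bandwidth (pixels) applied to the
#'   FRET and CFP channels before the ratio is taken; default 1.0.
#' @param frame_interval Imaging interval in minutes (default 2). Internal
#'   computation is in pixels and frames; the interval is applied only when
#'   converting to per-minute units.
#' @return A list with class `smoothing_config`.
#' @export
smoothing_config <- function(sg_window = 11L, sg_order = 2L,
                             fit_radius_erk = 10, fit_radius_vel = 10,
                             kde_sigma = 25, image_sigma = 1.0,
                             frame_interval = 2) {
  stop_if_not_scalar_num(sg_window, "sg_window", positive = TRUE, integer = TRUE)
  stop_if_not_scalar_num(sg_order, "sg_order", positive = TRUE, integer = TRUE)
  if (sg_window %% 2L == 0L || sg_window <= sg_order)
    stop("'sg_window' must be odd and greater than 'sg_order'")
  for (nm in c("fit_radius_erk", "fit_radius_vel", "kde_sigma", "image_sigma",
               "frame_interval"))
    stop_if_not_scalar_num(get(nm), nm, positive = TRUE)
  structure(list(sg_window = as.integer(sg_window),
                 sg_order = as.integer(sg_order),
                 fit_radius_erk = fit_radius_erk,
                 fit_radius_vel = fit_radius_vel,
                 kde_sigma = kde_sigma, image_sigma = image_sigma,
                 frame_interval = frame_interval),
            class = "smoothing_config")
}

# Coefficient matrix C of the centred Savitzky-Golay fit: row k+1 applied to a
# window of values yields the k-th polynomial coefficient b_k of the local
# least-squares fit y ~ sum_k b_k * m^k over offsets m = -h..h.
sg_coefficients <- function(window, order) {
  h <- (window - 1L) %/% 2L
  m <- -h:h
  A <- outer(m, 0:order, `^`)
  solve(crossprod(A), t(A))
}

#' Savitzky-Golay velocities and accelerations of one track
#'
#' Fits a centred least-squares polynomial of order `sg_order` to positions in
#' a sliding window of `sg_window` frames and returns its analytic first and
#' second temporal derivatives: velocity in px/frame and acceleration in
#' px/frame^2, for both axes. Frames lacking a full centred window are dropped
#' (no mirroring), losing `(sg_window - 1)/2` frames at each end.
#'
#' @param track Rows of a track table for a single cell, frame-contiguous.
#' @param cfg A [smoothing_config()].
#' @return Data frame with columns `cell_id`, `frame`, `vx`, `vy`, `ax`, `ay`.
#' @export
savgol_derivatives <- function(track, cfg = smoothing_config()) {
  w <- cfg$sg_window
  h <- (w - 1L) %/% 2L
  n <- nrow(track)
  if (length(unique(track$cell_id)) != 1L)
    stop("savgol_derivatives() expects a single cell's track")
  if (n < w)
    stop(sprintf("track '%s' has %d frames but the Savitzky-Golay window is %d",
                 track$cell_id[1L], n, w))
  C <- sg_coefficients(w, cfg$sg_order)
  idx <- (h + 1L):(n - h)
  win <- outer(idx, -h:h, `+`)
  Wx <- matrix(track$x_px[win], nrow = length(idx))
  Wy <- matrix(track$y_px[win], nrow = length(idx))
  vel <- C[2L, ]
  acc <- 2 * C[3L, ]
  data.frame(cell_id = track$cell_id[idx], frame = track$frame[idx],
             vx = drop(Wx %*% vel), vy = drop(Wy %*% vel),
             ax = drop(Wx %*% acc), ay = drop(Wy %*% acc),
             stringsAsFactors = FALSE)
}

#' Convert frame-based derivatives to per-minute units
#'
#' @param deriv Output of [savgol_derivatives()].
#' @param frame_interval Minutes per frame.
#' @return The same data frame with velocities in px/min and accelerations in
#'   px/min^2.
#' @export
derivatives_per_minute <- function(deriv, frame_interval = 2) {
  stop_if_not_scalar_num(frame_interval, "frame_interval", positive = TRUE)
  deriv$vx <- deriv$vx / frame_interval
  deriv$vy <- deriv$vy / frame_interval
  deriv$ax <- deriv$ax / frame_interval^2
  deriv$ay <- deriv$ay / frame_interval^2
  deriv
}

#' Local quadratic surface fit at a point
#'
#' Least-squares fit of the full two-dimensional quadratic
#' `f(u, v) = b0 + b1 u + b2 v + b3 u^2 + b4 uv + b5 v^2` (coordinates
#' centred at `center`) to the values of neighbors within `radius`, returning
#' the analytic value, gradient and pure second derivatives of the fitted
#' surface at the centre. The focal point's own sample, when present among the
#' neighbors, participates in the fit.
#'
#' @param center Numeric length-2 vector (x, y) in pixels.
#' @param points Numeric matrix (n x 2) of sample positions.
#' @param values Numeric vector of sampled field values at `points`.
#' @param radius Inclusion radius in pixels.
#' @return List with `usable` (logical), `n_points`, `value`,
#'   `gradient` (length 2) and `second` (c(d2/dx2, d2/dy2)). When fewer than
#'   six in-radius points exist (or the design is rank-deficient) the record is
#'   flagged unusable rather than silently zeroed.
#' @export
local_quadratic_fit <- function(center, points, values, radius) {
  points <- matrix(as.numeric(points), ncol = 2L)
  unusable <- function(n) list(usable = FALSE, n_points = n, value = NA_real_,
                               gradient = c(NA_real_, NA_real_),
                               second = c(NA_real_, NA_real_))
  d2 <- (points[, 1L] - center[1L])^2 + (points[, 2L] - center[2L])^2
  keep <- which(d2 <= radius^2)
  if (length(keep) < 6L) return(unusable(length(keep)))
  u <- points[keep, 1L] - center[1L]
  v <- points[keep, 2L] - center[2L]
  X <- cbind(1, u, v, u * u, u * v, v * v)
  qx <- qr(X)
  if (qx$rank < 6L) return(unusable(length(keep)))
  b <- qr.coef(qx, values[keep])
  list(usable = TRUE, n_points = length(keep), value = unname(b[1L]),
       gradient = unname(b[2:3]), second = unname(c(2 * b[4L], 2 * b[6L])))
}

#' Gaussian kernel-density estimate of the cell-density field
#'
#' The density at a query point q is
#' `rho(q) = sum_cells (2 pi sigma^2)^-1 exp(-|q - p|^2 / (2 sigma^2))`,
#' in cells per px^2; the focal cell's own kernel is included. The field
#' integrates to the number of cells.
#'
#' @param positions Numeric matrix (n x 2) of cell positions in the frame.
#' @param query Numeric matrix (m x 2) of query points.
#' @param kde_sigma Kernel bandwidth in pixels.
#' @return Numeric vector of densities at the query points (zeros for an
#'   empty frame).
#' @export
kde_density <- function(positions, query, kde_sigma = 25) {
  stop_if_not_scalar_num(kde_sigma, "kde_sigma", positive = TRUE)
  query <- matrix(as.numeric(query), ncol = 2L)
  if (is.null(positions) || NROW(positions) == 0L)
    return(rep(0, nrow(query)))
  positions <- matrix(as.numeric(positions), ncol = 2L)
  dx <- outer(query[, 1L], positions[, 1L], `-`)
  dy <- outer(query[, 2L], positions[, 2L], `-`)
  rowSums(exp(-(dx * dx + dy * dy) / (2 * kde_sigma^2))) / (2 * pi * kde_sigma^2)
}
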