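#' Parameters of the 1D spring-particle epithelium
#'
#' Cells are point particles on a line, connected to their index neighbors by
#' Hookean springs whose rest length is the sum of the two cell radii. ERK
#' activity modulates the cell radius and the substrate friction:
#' `mu_i = mu0 * exp(-beta * ERK_i)` and, depending on the radius rule,
#' `R_i = R0 * (1 + alpha * ERK_i)` (instantaneous) or
#' `R_i = R0 * (1 + alpha * dERK_i/dt)` (derivative; the time derivative is
#' taken analytically from the ERK kinetics, not finite-differenced).
#'
#' @param k Spring constant (min^-2), > 0.
#' @param mu0 Basal friction (min^-1), >= 0.
#' @param R0 Basal cell radius (length units).
#' @param alpha ERK-to-radius gain.
#' @param beta ERK-to-friction gain.
#' @param sigma ERK decay rate (min^-1), > 0.
#' @param eta Neighbor viscosity coefficient (default 0; the Fig-style chain
#'   model omits it).
#' @param n_cells Number of cells (>= 2).
#' @param radius_rule `"instantaneous"` or `"derivative"`.
#' @return A list with class `spring_params`.
#' @export
spring_params <- function(k = 2, mu0 = 10, R0 = 0.5, alpha = 1.5, beta = 2.5,
                          sigma = 0.1, eta = 0, n_cells = 100L,
                          radius_rule = c("instantaneous", "derivative")) {
  radius_rule <- match.arg(radius_rule)
  stop_if_not_scalar_num(k, "k", positive = TRUE)
  stop_if_not_scalar_num(sigma, "sigma", positive = TRUE)
  stop_if_not_scalar_num(mu0, "mu0")
  if (mu0 < 0) stop("'mu0' must be >= 0")
  stop_if_not_scalar_num(n_cells, "n_cells", positive = TRUE, integer = TRUE)
  if (n_cells < 2L) stop("'n_cells' must be >= 2")
  structure(list(k = k, mu0 = mu0, R0 = R0, alpha = alpha, beta = beta,
                 sigma = sigma, eta = eta, n_cells = as.integer(n_cells),
                 radius_rule = radius_rule),
            class = "spring_params")
}

#' Optogenetic illumination schedule
#'
#' A band of `band_width` cells (in cell-index units) whose centre moves at
#' `sweep_velocity` cells per minute. Cells inside the band receive light
#' (`L_i = 1`), others none. The default start places the band centre at the
#' rightmost cell for a leftward sweep (at the leftmost for rightward), so
#' the band enters the chain from the edge.
#'
#' @param sweep_velocity Band speed in cell indices per minute (default 0.1).
#' @param band_width Band width in cells (default 30).
#' @param direction `"leftward"` (decreasing index; the wound-edge wave) or
#'   `"rightward"`.
#' @param start Initial band-centre index; `NULL` for the edge default.
#' @return A list with class `illumination_schedule`.
#' @export
illumination_schedule <- function(sweep_velocity = 0.1, band_width = 30,
                                  direction = c("leftward", "rightward"),
                                  start = NULL) {
  direction <- match.arg(direction)
  stop_if_not_scalar_num(sweep_velocity, "sweep_velocity")
  stop_if_not_scalar_num(band_width, "band_width", positive = TRUE)
  if (band_width < 1) stop("'band_width' must be >= 1")
  structure(list(sweep_velocity = sweep_velocity, band_width = band_width,
                 direction = direction, start = start),
            class = "illumination_schedule")
}

# Light intensity vector L_i(t) for an n-cell chain.
light_at <- function(schedule, t, n) {
  start <- schedule$start %||% if (schedule$direction == "leftward") n else 1L
  step <- if (schedule$direction == "leftward") -1 else 1
  centre <- start + step * schedule$sweep_velocity * t
  as.numeric(abs(seq_len(n) - centre) <= schedule$band_width / 2)
}

# ERK kinetics: relaxation toward the unit-normalized light drive,
# dERK/dt = -sigma * (ERK - L). Illuminated cells approach ERK = 1 with
# time constant 1/sigma.
erk_rate <- function(erk, light, sigma) -sigma * (erk - light)

#' One explicit integration step of the ERK kinetics
#'
#' @param state List with at least `erk` (per-cell ERK) and `t` (minutes).
#' @param schedule An [illumination_schedule()].
#' @param sigma ERK decay rate (min^-1).
#' @param dt Time step (min), > 0.
#' @return The state with `erk` advanced by one fourth-order step and `t`
#'   incremented.
#' @export
erk_step <- function(state, schedule, sigma, dt) {
  stop_if_not_scalar_num(dt, "dt", positive = TRUE)
  n <- length(state$erk)
  f <- function(t, e) erk_rate(e, light_at(schedule, t, n), sigma)
  t <- state$t %||% 0
  k1 <- f(t, state$erk)
  k2 <- f(t + dt / 2, state$erk + dt / 2 * k1)
  k3 <- f(t + dt / 2, state$erk + dt / 2 * k2)
  k4 <- f(t + dt, state$erk + dt * k3)
  state$erk <- state$erk + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  state$t <- t + dt
  state
}

#' Spring-chain accelerations
#'
#' Computes `dv_i/dt = -mu_i v_i + k (x_{i+1} - x_i) - k (R_i + R_{i+1})
#' - k (x_i - x_{i-1}) + k (R_i + R_{i-1})`, with end cells coupled only to
#' their single existing neighbor, plus the optional neighbor-viscosity term
#' `eta (v_{i+1} - 2 v_i + v_{i-1})` (one-sided at the ends). Aborts if any
#' neighboring pair has crossed.
#'
#' @param state List with `x`, `v`, `erk` (equal-length vectors) and
#'   optionally `light` (defaults to darkness).
#' @param params A [spring_params()].
#' @return Acceleration vector.
#' @export
spring_forces <- function(state, params) {
  x <- state$x
  v <- state$v
  erk <- state$erk
  n <- length(x)
  if (any(diff(x) <= 0))
    stop("cell order violated (crossing) at index ",
         which(diff(x) <= 0)[1L])
  light <- state$light %||% numeric(n)
  R <- if (params$radius_rule == "derivative")
    params$R0 * (1 + params$alpha * erk_rate(erk, light, params$sigma))
  else
    params$R0 * (1 + params$alpha * erk)
  mu <- params$mu0 * exp(-params$beta * erk)
  d <- diff(x)
  f_right <- params$k * (d - (R[-n] + R[-1L]))
  a <- -mu * v
  a[-n] <- a[-n] + f_right
  a[-1L] <- a[-1L] - f_right
  if (params$eta != 0) {
    lap <- c(v[2L] - v[1L],
             diff(v, lag = 1L)[-1L] - diff(v, lag = 1L)[-(n - 1L)],
             v[n - 1L] - v[n])
    a <- a + params$eta * lap
  }
  a
}

#' Run the spring-particle simulation
#'
#' Fixed-step fourth-order (classical Runge-Kutta) integration of positions,
#' velocities and ERK. Cells start at rest, uniformly spaced at `2 R0`, with
#' `ERK = 0`, unless initial conditions are supplied. State is recorded every
#' `record_interval` minutes; four kymograph fields are derived along the
#' chain: ERK, its time derivative, and the spatial gradients of both.
#'
#' @param params A [spring_params()].
#' @param schedule An [illumination_schedule()].
#' @param duration Total simulated time (min), > 0.
#' @param dt Integration step (min), default 0.01.
#' @param record_interval Output cadence (min), default 2 (the imaging
#'   interval); must be a multiple of `dt`.
#' @param x0,v0,erk0 Optional initial state vectors.
#' @return A list with class `spring_simulation`: `time`, matrices `x`, `v`,
#'   `erk` (time x cell), `kymographs` (list `erk`, `derk_dt`, `derk_dx`,
#'   `dderk_dt_dx`), `params`, `schedule`, `dt`.
#' @export
run_spring_simulation <- function(params, schedule, duration, dt = 0.01,
                                  record_interval = 2,
                                  x0 = NULL, v0 = NULL, erk0 = NULL) {
  stop_if_not_scalar_num(duration, "duration", positive = TRUE)
  stop_if_not_scalar_num(dt, "dt", positive = TRUE)
  n <- params$n_cells
  rec_n <- round(record_interval / dt)
  if (abs(rec_n * dt - record_interval) > 1e-9)
    stop("'record_interval' must be a multiple of 'dt'")
  x <- x0 %||% (2 * params$R0 * (seq_len(n) - 1))
  v <- v0 %||% numeric(n)
  e <- erk0 %||% numeric(n)
  n_steps <- round(duration / dt)
  n_rec <- n_steps %/% rec_n + 1L
  X <- matrix(NA_real_, n_rec, n)
  V <- X
  E <- X
  Tm <- numeric(n_rec)
  X[1L, ] <- x
  V[1L, ] <- v
  E[1L, ] <- e

  deriv <- function(t, x, v, e) {
    light <- light_at(schedule, t, n)
    a <- spring_forces(list(x = x, v = v, erk = e, light = light), params)
    list(dx = v, dv = a, de = erk_rate(e, light, params$sigma))
  }
  t <- 0
  ri <- 1L
  for (s in seq_len(n_steps)) {
    k1 <- deriv(t, x, v, e)
    k2 <- deriv(t + dt / 2, x + dt / 2 * k1$dx, v + dt / 2 * k1$dv,
                e + dt / 2 * k1$de)
    k3 <- deriv(t + dt / 2, x + dt / 2 * k2$dx, v + dt / 2 * k2$dv,
                e + dt / 2 * k2$de)
    k4 <- deriv(t + dt, x + dt * k3$dx, v + dt * k3$dv, e + dt * k3$de)
    x <- x + dt / 6 * (k1$dx + 2 * k2$dx + 2 * k3$dx + k4$dx)
    v <- v + dt / 6 * (k1$dv + 2 * k2$dv + 2 * k3$dv + k4$dv)
    e <- e + dt / 6 * (k1$de + 2 * k2$de + 2 * k3$de + k4$de)
    t <- s * dt
    if (!all(is.finite(x)) || !all(is.finite(v)))
      stop("simulation became non-finite at t = ", signif(t, 6),
           " min; reduce dt = ", dt)
    if (any(diff(x) <= 0))
      stop("cells ", which(diff(x) <= 0)[1L], " and ",
           which(diff(x) <= 0)[1L] + 1L, " crossed at t = ",
           signif(t, 6), " min")
    if (s %% rec_n == 0L) {
      ri <- ri + 1L
      X[ri, ] <- x
      V[ri, ] <- v
      E[ri, ] <- e
      Tm[ri] <- t
    }
  }
  X <- X[seq_len(ri), , drop = FALSE]
  V <- V[seq_len(ri), , drop = FALSE]
  E <- E[seq_len(ri), , drop = FALSE]
  Tm <- Tm[seq_len(ri)]

  dEdt <- t(vapply(seq_len(ri), function(i)
    erk_rate(E[i, ], light_at(schedule, Tm[i], n), params$sigma),
    numeric(n)))
  grad_chain <- function(M) {
    G <- M
    for (i in seq_len(nrow(M))) {
      xi <- X[i, ]
      G[i, ] <- c((M[i, 2L] - M[i, 1L]) / (xi[2L] - xi[1L]),
                  (M[i, -(1:2)] - M[i, -((n - 1L):n)]) /
                    (xi[-(1:2)] - xi[-((n - 1L):n)]),
                  (M[i, n] - M[i, n - 1L]) / (xi[n] - xi[n - 1L]))
    }
    G
  }
  structure(list(time = Tm, x = X, v = V, erk = E,
                 kymographs = list(erk = E, derk_dt = dEdt,
                                   derk_dx = grad_chain(E),
                                   dderk_dt_dx = grad_chain(dEdt)),
                 params = params, schedule = schedule, dt = dt),
            class = "spring_simulation")
}

#' @export
print.spring_simulation <- function(x, ...) {
  cat(sprintf("Spring-chain simulation: %d cells, %g min (%s radius rule)\n",
              ncol(x$x), max(x$time), x$params$radius_rule))
  invisible(x)
}

#' Convert a simulation into a tracked-cell table
#'
#' Samples positions and ERK at the imaging cadence, maps the chain
#' coordinate to the orthogonal (x) axis with an optional pixel scale, and
#' assigns each cell a constant y offset (jitter) so that the 2D feature
#' extraction runs on the result.
#'
#' @param sim A [run_spring_simulation()] result.
#' @param frame_interval Imaging cadence (min); must be a multiple of the
#'   simulation's record interval.
#' @param px_per_unit Pixels per chain length unit (default 1).
#' @param y_jitter_sd Standard deviation of the per-cell constant y offset in
#'   pixels (default 0).
#' @param seed Seed for the jitter.
#' @return A track table; frames are numbered from 1.
#' @export
tracks_from_simulation <- function(sim, frame_interval = 2, px_per_unit = 1,
                                   y_jitter_sd = 0, seed = NULL) {
  rec <- if (length(sim$time) > 1L) sim$time[2L] - sim$time[1L] else frame_interval
  stride <- round(frame_interval / rec)
  if (abs(stride * rec - frame_interval) > 1e-9 || stride < 1L)
    stop("'frame_interval' must be a positive multiple of the recording interval")
  rows <- seq(1L, nrow(sim$x), by = stride)
  # one frame per full imaging interval: 7 h at 2 min gives 210 frames
  n_frames <- max(1L, floor(max(sim$time) / frame_interval))
  rows <- rows[seq_len(min(length(rows), n_frames))]
  n <- ncol(sim$x)
  y <- local_seed(seed, if (y_jitter_sd > 0) stats::rnorm(n, 0, y_jitter_sd)
                  else numeric(n))
  ids <- sprintf("cell_%03d", seq_len(n))
  df <- data.frame(
    cell_id = rep(ids, each = length(rows)),
    frame = rep(seq_along(rows), times = n),
    x_px = as.vector(sim$x[rows, ]) * px_per_unit,
    y_px = rep(y, each = length(rows)),
    erk = as.vector(sim$erk[rows, ]),
    stringsAsFactors = FALSE)
  as_track_table(df)
}

#' Write a kymograph matrix as delimited text
#'
#' @param sim A [run_spring_simulation()] result.
#' @param field One of `"erk"`, `"derk_dt"`, `"derk_dx"`, `"dderk_dt_dx"`.
#' @param path Output path; rows are recorded times, columns cells.
#' @return The path, invisibly.
#' @export
write_kymograph <- function(sim, field, path) {
  field <- match.arg(field, names(sim$kymographs))
  M <- sim$kymographs[[field]]
  df <- data.frame(time_min = sim$time, M)
  names(df) <- c("time_min", sprintf("cell_%03d", seq_len(ncol(M))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
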