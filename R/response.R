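#' Lag specification of the convolutional model
#'
#' @param L Number of lag frames in each history kernel (default 20, roughly
#'   the inter-feature cross-correlation time of wound-healing data).
#' @param frame_interval Minutes per frame (default 2).
#' @return A list with class `lag_spec`.
#' @export
lag_spec <- function(L = 20L, frame_interval = 2) {
  stop_if_not_scalar_num(L, "L", positive = TRUE, integer = TRUE)
  stop_if_not_scalar_num(frame_interval, "frame_interval", positive = TRUE)
  structure(list(L = as.integer(L), frame_interval = frame_interval),
            class = "lag_spec")
}

kernel_names <- c("erk_grad", "rho_grad", "d2v_dx2", "d2v_dy2")

#' Response function of the convolutional acceleration model
#'
#' Represents the fitted law
#' `a(t) = w0 - w1 x1(t) + sum_i sum_tau w_i(tau) x_i(t - tau)` where
#' `x1` is the instantaneous velocity component (no history, so that the
#' trivial integration of acceleration cannot absorb the other inputs) and
#' the four kernels act on the ERK gradient, the density gradient and the two
#' velocity curvatures over `L` lag frames. The discrete convolution absorbs
#' the frame interval into the kernel values. Positive `w1` means
#' friction-like damping.
#'
#' @param w0 Bias (px/frame^2).
#' @param w1 Instantaneous velocity coefficient (frame^-1), friction sign
#'   convention (the model term is `-w1 x1`).
#' @param kernels Named list `erk_grad`, `rho_grad`, `d2v_dx2`, `d2v_dy2`,
#'   each a numeric vector of length `lag$L` (lag 0 first).
#' @param axis `"orthogonal"` or `"parallel"`.
#' @param lag A [lag_spec()].
#' @return A list with class `response_function`.
#' @export
response_function <- function(w0, w1, kernels, axis = "orthogonal",
                              lag = lag_spec()) {
  if (!axis %in% c("orthogonal", "parallel"))
    stop("'axis' must be \"orthogonal\" or \"parallel\"")
  if (!is.list(kernels) || !identical(sort(names(kernels)), sort(kernel_names)))
    stop("'kernels' must be a named list with elements: ",
         paste(kernel_names, collapse = ", "))
  kernels <- kernels[kernel_names]
  lens <- vapply(kernels, length, integer(1L))
  if (any(lens != lag$L))
    stop(sprintf("each kernel must have exactly L = %d entries", lag$L))
  structure(list(w0 = as.numeric(w0), w1 = as.numeric(w1),
                 kernels = lapply(kernels, as.numeric),
                 axis = axis, lag = lag),
            class = "response_function")
}

#' @export
print.response_function <- function(x, ...) {
  cat(sprintf("Response function (%s axis), L = %d lag frames (%g min/frame)\n",
              x$axis, x$lag$L, x$lag$frame_interval))
  cat(sprintf("  w0 (bias)      % .4g\n  w1 (velocity)  % .4g\n", x$w0, x$w1))
  for (k in kernel_names)
    cat(sprintf("  %-12s peak % .4g at lag %d, L2 %.4g\n", k,
                x$kernels[[k]][which.max(abs(x$kernels[[k]]))],
                which.max(abs(x$kernels[[k]])) - 1L,
                sqrt(sum(x$kernels[[k]]^2))))
  invisible(x)
}

# Coefficient vector in design order: [w0, beta1 = -w1, kernels...].
rf_theta <- function(rf) {
  c(rf$w0, -rf$w1, unlist(rf$kernels, use.names = FALSE))
}

theta_to_rf <- function(theta, axis, lag) {
  L <- lag$L
  if (length(theta) != 2L + 4L * L)
    stop(sprintf("coefficient vector has length %d, expected %d",
                 length(theta), 2L + 4L * L))
  ker <- lapply(seq_along(kernel_names), function(i)
    theta[(2L + (i - 1L) * L + 1L):(2L + i * L)])
  names(ker) <- kernel_names
  response_function(w0 = theta[1L], w1 = -theta[2L], kernels = ker,
                    axis = axis, lag = lag)
}

#' Flatten a response function to a similarity vector
#'
#' Fixed, versioned flattening order: `[w0][w1] erk_grad(0..L-1),
#' rho_grad(...), d2v_dx2(...), d2v_dy2(...)`. By default the bias is
#' excluded and the velocity coefficient included, matching how per-cell
#' response functions are compared.
#'
#' @param rf A response function.
#' @param include_bias Include `w0` (default `FALSE`).
#' @param include_velocity Include `w1` (default `TRUE`).
#' @return Numeric vector.
#' @export
flatten_rf <- function(rf, include_bias = FALSE, include_velocity = TRUE) {
  c(if (include_bias) rf$w0, if (include_velocity) rf$w1,
    unlist(rf$kernels, use.names = FALSE))
}

#' Mean of several response functions
#'
#' @param rfs List of response functions sharing axis and lag spec.
#' @return The element-wise arithmetic mean response function.
#' @export
mean_response_function <- function(rfs) {
  stopifnot(length(rfs) >= 1L)
  ker <- lapply(kernel_names, function(k)
    Reduce(`+`, lapply(rfs, function(r) r$kernels[[k]])) / length(rfs))
  names(ker) <- kernel_names
  response_function(
    w0 = mean(vapply(rfs, `[[`, numeric(1L), "w0")),
    w1 = mean(vapply(rfs, `[[`, numeric(1L), "w1")),
    kernels = ker, axis = rfs[[1L]]$axis, lag = rfs[[1L]]$lag)
}

#' Continuum-model coefficient mapping
#'
#' Maps the mechanical parameters of the coarse-grained tissue model to the
#' instantaneous regression coefficients, evaluated at a reference density
#' and ERK level (the mapping holds only under high-cell-density conditions):
#' velocity `-mu0 (1 - beta ERK)`, ERK gradient `-2 alpha k R0 / rho`,
#' density gradient `-k / rho^3`, and both velocity curvatures `eta / rho^2`.
#'
#' @param mu0 Basal friction (min^-1).
#' @param beta ERK-to-friction gain.
#' @param alpha ERK-to-radius gain.
#' @param k Spring constant (min^-2).
#' @param R0 Basal cell radius.
#' @param eta Tissue viscosity coefficient.
#' @param rho_ref Reference density (> 0).
#' @param erk_ref Reference ERK level.
#' @return Named list `c_vel`, `c_erk`, `c_rho`, `c_visc_x`, `c_visc_y`.
#' @export
continuum_coefficients <- function(mu0, beta, alpha, k, R0, eta = 0,
                                   rho_ref, erk_ref = 0) {
  stop_if_not_scalar_num(rho_ref, "rho_ref", positive = TRUE)
  list(c_vel = -mu0 * (1 - beta * erk_ref),
       c_erk = -2 * alpha * k * R0 / rho_ref,
       c_rho = -k / rho_ref^3,
       c_visc_x = eta / rho_ref^2,
       c_visc_y = eta / rho_ref^2)
}

#' Serialize a response function to structured text
#'
#' Plain-text key/value format with a format version; kernels are written as
#' space-separated full-precision values, one line per input feature. The
#' round trip is lossless and byte-reproducible.
#'
#' @param rf A response function.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_response_function <- function(rf, path) {
  lines <- c(
    "format_version: 1",
    paste0("axis: ", rf$axis),
    paste0("lag_frames: ", rf$lag$L),
    paste0("frame_interval: ", fmt_num(rf$lag$frame_interval)),
    paste0("w0: ", fmt_num(rf$w0)),
    paste0("w1: ", fmt_num(rf$w1)),
    vapply(kernel_names, function(k)
      paste0("kernel ", k, ": ",
             paste(vapply(rf$kernels[[k]], fmt_num, character(1L)),
                   collapse = " ")),
      character(1L)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_response_function
#' @export
read_response_function <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  lines <- readLines(path)
  get_field <- function(key) {
    hit <- grep(paste0("^", key, ": "), lines, value = TRUE)
    if (!length(hit)) stop("model file is missing field '", key, "'")
    sub(paste0("^", key, ": "), "", hit[1L])
  }
  ver <- get_field("format_version")
  if (ver != "1") stop("unsupported model file format version: ", ver)
  lag <- lag_spec(L = as.integer(get_field("lag_frames")),
                  frame_interval = as.numeric(get_field("frame_interval")))
  ker <- lapply(kernel_names, function(k)
    as.numeric(strsplit(get_field(paste0("kernel ", k)), " ", fixed = TRUE)[[1L]]))
  names(ker) <- kernel_names
  response_function(w0 = as.numeric(get_field("w0")),
                    w1 = as.numeric(get_field("w1")),
                    kernels = ker, axis = get_field("axis"), lag = lag)
}
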