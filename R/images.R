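#' Gaussian blur of an image matrix
#'
#' Separable discrete Gaussian convolution with kernel truncated at
#' `ceiling(3 * sigma)` and replicate (edge-extension) padding. Used to
#' attenuate high-frequency noise in the FRET and CFP channels before the
#' ratio is computed.
#'
#' @param img Numeric matrix.
#' @param sigma Kernel standard deviation in pixels; `0` returns the input.
#' @return Smoothed matrix of the same dimensions.
#' @export
gaussian_blur <- function(img, sigma) {
  if (sigma < 0) stop("'sigma' must be >= 0")
  if (sigma == 0) return(img)
  r <- ceiling(3 * sigma)
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  blur_axis <- function(m, axis) {
    n <- dim(m)[axis]
    idx <- c(rep(1L, r), seq_len(n), rep(n, r))
    P <- if (axis == 1L) m[idx, , drop = FALSE] else m[, idx, drop = FALSE]
    out <- matrix(0, nrow(m), ncol(m))
    for (t in seq_along(k)) {
      sl <- t:(t + n - 1L)
      out <- out + k[t] * (if (axis == 1L) P[sl, , drop = FALSE]
                           else P[, sl, drop = FALSE])
    }
    out
  }
  blur_axis(blur_axis(img, 1L), 2L)
}

#' Pixel-wise FRET/CFP ratio images
#'
#' Each frame of both channels is Gaussian-smoothed (`cfg$image_sigma`), the
#' channel background is subtracted, and the pixel-wise ratio
#' (FRET - bg) / (CFP - bg) is formed. Pixels whose denominator is not
#' positive after background subtraction are masked as `NA`; their count is
#' reported in the `n_masked` attribute.
#'
#' @param fret_stack,cfp_stack Image stacks of identical shape: a list of
#'   matrices or a 3-d array (rows x cols x frames).
#' @param background Length-2 numeric, background level of the FRET and CFP
#'   channels (default `c(0, 0)`).
#' @param cfg A [smoothing_config()]; only `image_sigma` is used.
#' @return A stack (same container type as the input) of ERK ratio frames
#'   with attribute `n_masked`.
#' @export
ratio_image <- function(fret_stack, cfp_stack, background = c(0, 0),
                        cfg = smoothing_config()) {
  as_list <- function(s) {
    if (is.list(s)) lapply(s, as.matrix)
    else if (is.array(s) && length(dim(s)) == 3L)
      lapply(seq_len(dim(s)[3L]), function(i) s[, , i])
    else if (is.matrix(s)) list(s)
    else stop("image stacks must be matrices, lists of matrices or 3-d arrays")
  }
  f <- as_list(fret_stack)
  c_ <- as_list(cfp_stack)
  if (length(f) != length(c_) ||
      !all(vapply(seq_along(f), function(i) identical(dim(f[[i]]), dim(c_[[i]])),
                  logical(1L))))
    stop("FRET and CFP stacks must have identical shapes")
  n_masked <- 0L
  out <- lapply(seq_along(f), function(i) {
    num <- gaussian_blur(f[[i]], cfg$image_sigma) - background[1L]
    den <- gaussian_blur(c_[[i]], cfg$image_sigma) - background[2L]
    bad <- den <= 0
    n_masked <<- n_masked + sum(bad)
    r <- num / den
    r[bad] <- NA_real_
    r
  })
  if (is.array(fret_stack) && length(dim(fret_stack)) == 3L)
    out <- array(unlist(out), dim = dim(fret_stack))
  else if (is.matrix(fret_stack)) out <- out[[1L]]
  attr(out, "n_masked") <- n_masked
  out
}

#' Read a multi-page TIFF stack as a list of matrices
#'
#' @param path TIFF file path.
#' @return List of numeric matrices, one per page.
#' @export
read_tiff_stack <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("reading TIFF stacks requires the 'tiff' package")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # collapse grayscale-with-alpha
    as.matrix(p)
  })
}
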