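#' Assemble the per-cell, per-frame regression feature table
#'
#' Combines the trajectory and field operators into the inputs of the
#' convolutional acceleration model. For `axis = "orthogonal"` the record at
#' cell c, frame t holds
#' `x1 = v_x`, `x2 = dERK/dx`, `x3 = drho/dx`, `x4 = d2 v_x/dx2`,
#' `x5 = d2 v_x/dy2` and the target `accel = a_x`; for `axis = "parallel"`
#' the roles of x and y are exchanged consistently (velocity component v_y,
#' gradients along y, curvatures of v_y along x and y).
#'
#' Velocities and accelerations come from [savgol_derivatives()]; the ERK and
#' density gradients and the velocity curvatures from [local_quadratic_fit()]
#' over neighbors within the configured radii (scalar fields use
#' `fit_radius_erk`, the velocity field `fit_radius_vel`); the density field
#' from [kde_density()] evaluated at the cell positions themselves, so the
#' whole pipeline needs only the track table. Records with any unusable
#' constituent are dropped, never imputed; drop reasons are counted in the
#' `dropped` attribute.
#'
#' @param tracks A (filtered) track table.
#' @param cfg A [smoothing_config()].
#' @param axis `"orthogonal"` (to the wound; x) or `"parallel"` (y).
#' @return A data frame with class `feature_table`: columns `cell_id`,
#'   `frame`, `axis`, `accel`, `x1_vel`, `x2_erk_grad`, `x3_rho_grad`,
#'   `x4_d2v_dx2`, `x5_d2v_dy2`, `rho`; attributes `axis`, `dropped`,
#'   `frame_interval`.
#' @export
assemble_feature_table <- function(tracks, cfg = smoothing_config(),
                                   axis = c("orthogonal", "parallel")) {
  axis <- match.arg(axis)
  tracks <- as_track_table(tracks)
  if (nrow(tracks) == 0L) stop("no tracks supplied")
  dropped <- c(track_too_short = 0L, erk_fit_unusable = 0L,
               rho_fit_unusable = 0L, vel_fit_unusable = 0L)

  per_cell <- split(tracks, tracks$cell_id)
  sg <- vector("list", length(per_cell))
  names(sg) <- names(per_cell)
  for (cid in names(per_cell)) {
    tr <- per_cell[[cid]]
    if (nrow(tr) < cfg$sg_window) {
      dropped["track_too_short"] <- dropped["track_too_short"] + 1L
      next
    }
    sg[[cid]] <- savgol_derivatives(tr, cfg)
  }
  sg_all <- do.call(rbind, sg[!vapply(sg, is.null, logical(1L))])
  if (is.null(sg_all) || nrow(sg_all) == 0L)
    stop("no track is long enough for the Savitzky-Golay window")

  D <- merge(tracks, sg_all, by = c("cell_id", "frame"), all.x = TRUE)
  D <- D[order(D$frame, D$cell_id), , drop = FALSE]

  records <- vector("list", 512L)
  nrec <- 0L
  for (sub in split(D, D$frame)) {
    pos <- cbind(sub$x_px, sub$y_px)
    rho <- kde_density(pos, pos, cfg$kde_sigma)
    has_vel <- !is.na(sub$vx)
    vcomp <- if (axis == "orthogonal") sub$vx else sub$vy
    acomp <- if (axis == "orthogonal") sub$ax else sub$ay
    dir <- if (axis == "orthogonal") 1L else 2L
    for (i in which(has_vel)) {
      ctr <- pos[i, ]
      erk_fit <- local_quadratic_fit(ctr, pos, sub$erk, cfg$fit_radius_erk)
      if (!erk_fit$usable) {
        dropped["erk_fit_unusable"] <- dropped["erk_fit_unusable"] + 1L
        next
      }
      rho_fit <- local_quadratic_fit(ctr, pos, rho, cfg$fit_radius_erk)
      if (!rho_fit$usable) {
        dropped["rho_fit_unusable"] <- dropped["rho_fit_unusable"] + 1L
        next
      }
      vel_fit <- local_quadratic_fit(ctr, pos[has_vel, , drop = FALSE],
                                     vcomp[has_vel], cfg$fit_radius_vel)
      if (!vel_fit$usable) {
        dropped["vel_fit_unusable"] <- dropped["vel_fit_unusable"] + 1L
        next
      }
      nrec <- nrec + 1L
      if (nrec > length(records)) records <- c(records, vector("list", length(records)))
      records[[nrec]] <- data.frame(
        cell_id = sub$cell_id[i], frame = sub$frame[i], axis = axis,
        accel = acomp[i], x1_vel = vcomp[i],
        x2_erk_grad = erk_fit$gradient[dir],
        x3_rho_grad = rho_fit$gradient[dir],
        x4_d2v_dx2 = vel_fit$second[1L],
        x5_d2v_dy2 = vel_fit$second[2L],
        rho = rho[i], stringsAsFactors = FALSE)
    }
  }
  out <- if (nrec) do.call(rbind, records[seq_len(nrec)]) else
    data.frame(cell_id = character(0), frame = integer(0), axis = character(0),
               accel = numeric(0), x1_vel = numeric(0), x2_erk_grad = numeric(0),
               x3_rho_grad = numeric(0), x4_d2v_dx2 = numeric(0),
               x5_d2v_dy2 = numeric(0), rho = numeric(0))
  out <- out[order(out$cell_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("feature_table", "data.frame")
  attr(out, "axis") <- axis
  attr(out, "dropped") <- dropped
  attr(out, "frame_interval") <- cfg$frame_interval
  out
}

feature_columns <- c("x1_vel", "x2_erk_grad", "x3_rho_grad",
                     "x4_d2v_dx2", "x5_d2v_dy2")

#' Read/write feature tables as delimited text
#'
#' @param table A feature table.
#' @param path File path.
#' @param sep Field separator.
#' @return The path (write) or the feature table (read).
#' @export
write_feature_table <- function(table, path, sep = "\t") {
  utils::write.table(table, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("feature table file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  ax <- unique(df$axis)
  if (length(ax) != 1L)
    stop("feature table must contain a single axis, found: ",
         paste(ax, collapse = ", "))
  df$cell_id <- as.character(df$cell_id)
  class(df) <- c("feature_table", "data.frame")
  attr(df, "axis") <- ax
  df
}

#' Mean cross-correlation between input features across time lags
#'
#' For every ordered pair of features, computes the Pearson correlation
#' between one feature and the lagged copy of the other within each cell's
#' contiguous series, at every lag from `-max_lag` to `+max_lag` minutes, and
#' averages over cells. Cells whose series are too short for the requested lag
#' range are skipped and counted.
#'
#' @param table A feature table.
#' @param max_lag Maximum lag in minutes (default 100).
#' @param frame_interval Minutes per frame (default taken from the table, else 2).
#' @return Data frame `feature_a`, `feature_b`, `lag_frames`, `lag_min`,
#'   `correlation`, `n_cells`, with attribute `n_skipped`.
#' @export
feature_crosscorrelation <- function(table, max_lag = 100,
                                     frame_interval = NULL) {
  frame_interval <- frame_interval %||% attr(table, "frame_interval") %||% 2
  lag_f <- floor(max_lag / frame_interval)
  lags <- -lag_f:lag_f
  feats <- feature_columns
  n_skipped <- 0L
  acc <- array(0, dim = c(length(feats), length(feats), length(lags)))
  cnt <- array(0L, dim = dim(acc))
  for (sub in split(table, table$cell_id)) {
    sub <- sub[order(sub$frame), ]
    n <- nrow(sub)
    if (n <= 2L * lag_f) {
      n_skipped <- n_skipped + 1L
      next
    }
    M <- as.matrix(sub[feats])
    for (a in seq_along(feats)) for (b in seq_along(feats)) {
      r <- lagged_pearson(M[, a], M[, b], lags)
      ok <- !is.na(r)
      acc[a, b, ok] <- acc[a, b, ok] + r[ok]
      cnt[a, b, ok] <- cnt[a, b, ok] + 1L
    }
  }
  corr <- acc / pmax(cnt, 1L)
  corr[cnt == 0L] <- NA_real_
  out <- expand.grid(feature_a = feats, feature_b = feats,
                     lag_frames = lags, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  out$lag_min <- out$lag_frames * frame_interval
  out$correlation <- as.vector(corr)
  out$n_cells <- as.vector(cnt)
  attr(out, "n_skipped") <- n_skipped
  out
}

# cor(a[t], b[t + lag]) for each lag; NA when either window is constant.
lagged_pearson <- function(a, b, lags) {
  n <- length(a)
  vapply(lags, function(l) {
    if (l >= 0) {
      x <- a[seq_len(n - l)]
      y <- b[seq_len(n - l) + l]
    } else {
      x <- a[seq_len(n + l) - l]
      y <- b[seq_len(n + l)]
    }
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, numeric(1L))
}
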