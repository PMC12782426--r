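#' Ridge-regression configuration
#'
#' @param lambda Ridge strength; `NULL` to select by [cv_lambda()].
#' @param grid Broad-stage geometric lambda grid (default `10^-4 .. 10^4`).
#' @param folds Number of cross-validation folds (default 5).
#' @param grouping `"sample"` (rows assigned to folds independently) or
#'   `"cell"` (whole cells held out together, the grouped variant).
#' @param seed Seed fixing the fold assignment.
#' @param standardize Z-score the non-intercept columns before fitting and
#'   rescale the coefficients back to raw units (default `FALSE`; the
#'   reported lambda then acts on raw-unit coefficients).
#' @return A list with class `ridge_config`.
#' @export
ridge_config <- function(lambda = NULL, grid = NULL, folds = 5L,
                         grouping = c("sample", "cell"), seed = 1L,
                         standardize = FALSE) {
  grouping <- match.arg(grouping)
  stop_if_not_scalar_num(folds, "folds", positive = TRUE, integer = TRUE)
  if (folds < 2L) stop("'folds' must be >= 2")
  if (!is.null(lambda)) stop_if_not_scalar_num(lambda, "lambda", positive = TRUE)
  if (!is.null(grid) && any(grid <= 0)) stop("all 'grid' values must be > 0")
  structure(list(lambda = lambda, grid = grid, folds = as.integer(folds),
                 grouping = grouping, seed = seed,
                 standardize = isTRUE(standardize)),
            class = "ridge_config")
}

#' Build the lagged design matrix of the convolutional model
#'
#' One row per (cell, frame) with at least `L` frames of history available
#' within that cell:
#' `[1, x1(t), x2(t), x2(t-1), ..., x2(t-L+1), x3(t), ..., x5(t-L+1)]`
#' (length `2 + 4L`), target `accel(t)`. Rows never mix cells; the
#' convolution is discretized as `sum_{tau=0}^{L-1} w(tau) x(t - tau)` with
#' the frame interval absorbed into the kernel.
#'
#' @param table A feature table with frame-contiguous records per cell.
#' @param lag A [lag_spec()].
#' @return List with `X` (design matrix), `y` (target vector) and `index`
#'   (data frame of `cell_id`, `frame` per row); attributes `axis` and `lag`.
#' @export
build_design <- function(table, lag = lag_spec()) {
  L <- lag$L
  table <- table[order(table$cell_id, table$frame), , drop = FALSE]
  cells <- split(table, table$cell_id)
  parts <- vector("list", length(cells))
  idx <- vector("list", length(cells))
  j <- 0L
  for (cid in names(cells)) {
    sub <- cells[[cid]]
    n <- nrow(sub)
    if (n > 1L && any(diff(sub$frame) != 1L))
      stop("frames are not contiguous within cell '", cid, "'")
    if (n < L) next
    lag_block <- function(x) stats::embed(x, L)
    X <- cbind(1, sub$x1_vel[L:n],
               lag_block(sub$x2_erk_grad),
               lag_block(sub$x3_rho_grad),
               lag_block(sub$x4_d2v_dx2),
               lag_block(sub$x5_d2v_dy2))
    j <- j + 1L
    parts[[j]] <- X
    idx[[j]] <- data.frame(cell_id = cid, frame = sub$frame[L:n],
                           y = sub$accel[L:n], stringsAsFactors = FALSE)
  }
  if (j == 0L) stop("no cell has at least L = ", L, " usable frames")
  X <- do.call(rbind, parts[seq_len(j)])
  ix <- do.call(rbind, idx[seq_len(j)])
  if (!all(is.finite(X)) || !all(is.finite(ix$y)))
    stop("non-finite entries in the design or target")
  out <- list(X = X, y = ix$y, index = ix[c("cell_id", "frame")])
  attr(out, "axis") <- attr(table, "axis") %||% unique(table$axis)[1L]
  attr(out, "lag") <- lag
  out
}

#' Penalized normal-equations ridge solver
#'
#' Minimizes `||y - X theta||^2 + lambda * ||theta_pen||^2` where the penalty
#' covers the columns flagged in `penalized` (by default all but the first,
#' leaving the bias unpenalized).
#'
#' @param X Design matrix.
#' @param y Target vector.
#' @param lambda Ridge strength (>= 0).
#' @param penalized Logical vector over columns.
#' @return Coefficient vector.
#' @export
ridge_solve <- function(X, y, lambda,
                        penalized = c(FALSE, rep(TRUE, ncol(X) - 1L))) {
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("non-finite entries in the design or target")
  if (lambda < 0) stop("'lambda' must be >= 0")
  A <- crossprod(X)
  diag(A) <- diag(A) + lambda * as.numeric(penalized)
  drop(solve(A, crossprod(X, y)))
}

#' Fit a response function by ridge regression
#'
#' @param design Output of [build_design()].
#' @param lambda Ridge strength.
#' @param standardize Z-score non-intercept columns before fitting; the
#'   returned coefficients are rescaled to raw units.
#' @return A [response_function()].
#' @export
ridge_fit <- function(design, lambda, standardize = FALSE) {
  X <- design$X
  y <- design$y
  if (standardize) {
    mu <- colMeans(X[, -1L, drop = FALSE])
    sd_ <- apply(X[, -1L, drop = FALSE], 2L, stats::sd)
    sd_[sd_ == 0] <- 1
    Xs <- cbind(1, sweep(sweep(X[, -1L, drop = FALSE], 2L, mu), 2L, sd_, `/`))
    th <- ridge_solve(Xs, y, lambda)
    beta <- th[-1L] / sd_
    theta <- c(th[1L] - sum(beta * mu), beta)
  } else {
    theta <- ridge_solve(X, y, lambda)
  }
  theta_to_rf(theta, attr(design, "axis") %||% "orthogonal", attr(design, "lag"))
}

# Deterministic fold assignment; returns integer fold id per design row.
assign_folds <- function(design, cfg) {
  n <- nrow(design$X)
  local_seed(cfg$seed, {
    if (cfg$grouping == "cell") {
      cells <- unique(design$index$cell_id)
      if (length(cells) < cfg$folds)
        stop(sprintf("grouped CV needs at least %d cells, got %d",
                     cfg$folds, length(cells)))
      fold_of_cell <- sample(rep_len(seq_len(cfg$folds), length(cells)))
      names(fold_of_cell) <- cells
      unname(fold_of_cell[design$index$cell_id])
    } else {
      if (n < cfg$folds)
        stop(sprintf("CV needs at least %d rows, got %d", cfg$folds, n))
      sample(rep_len(seq_len(cfg$folds), n))
    }
  })
}

#' Select the ridge strength by two-stage cross-validated search
#'
#' Stage one scans a broad geometric grid (`10^-4 .. 10^4` by default); stage
#' two rescans one decade either side of the broad minimum at 20 points per
#' decade. The mean held-out squared error decides; exact ties break toward
#' the larger lambda (more regularization). Deterministic given the seed.
#'
#' @param design Output of [build_design()].
#' @param cfg A [ridge_config()].
#' @return List with `lambda`, `curve` (stage, lambda, cv_error) and `folds`.
#' @export
cv_lambda <- function(design, cfg = ridge_config()) {
  fold <- assign_folds(design, cfg)
  X <- design$X
  y <- design$y
  k <- cfg$folds
  # Precompute per-fold Gram pieces so each lambda costs one small solve.
  XtX_all <- crossprod(X)
  Xty_all <- crossprod(X, y)
  fold_parts <- lapply(seq_len(k), function(f) {
    sel <- fold == f
    Xv <- X[sel, , drop = FALSE]
    list(XtX = XtX_all - crossprod(Xv),
         Xty = Xty_all - crossprod(Xv, y[sel]),
         Xv = Xv, yv = y[sel])
  })
  pen <- c(0, rep(1, ncol(X) - 1L))
  cv_err <- function(lams) {
    vapply(lams, function(lam) {
      sse <- 0
      for (fp in fold_parts) {
        A <- fp$XtX
        diag(A) <- diag(A) + lam * pen
        beta <- solve(A, fp$Xty)
        sse <- sse + sum((fp$yv - fp$Xv %*% beta)^2)
      }
      sse / length(y)
    }, numeric(1L))
  }
  pick <- function(lams, errs) lams[max(which(errs == min(errs)))]
  grid1 <- cfg$grid %||% 10^seq(-4, 4, length.out = 17L)
  err1 <- cv_err(grid1)
  best1 <- pick(grid1, err1)
  grid2 <- 10^seq(log10(best1) - 1, log10(best1) + 1, length.out = 41L)
  err2 <- cv_err(grid2)
  best <- pick(grid2, err2)
  list(lambda = best,
       curve = data.frame(
         stage = rep(1:2, c(length(grid1), length(grid2))),
         lambda = c(grid1, grid2), cv_error = c(err1, err2)),
       folds = fold)
}

#' Per-fold response functions under grouped cross-validation
#'
#' Fits one response function on each leave-cells-out training set of a
#' cell-grouped k-fold split and reports the pairwise cosine similarity of
#' the fold kernels, a stability diagnostic of the fitted law.
#'
#' @param table A feature table.
#' @param lag A [lag_spec()].
#' @param cfg A [ridge_config()] with `grouping = "cell"`; `cfg$lambda` is
#'   used when given, otherwise selected once by [cv_lambda()] on the full
#'   design.
#' @return List with `rfs` (per-fold response functions), `similarity`
#'   (k x k cosine-similarity matrix) and `lambda`.
#' @export
grouped_cv_stability <- function(table, lag = lag_spec(),
                                 cfg = ridge_config(grouping = "cell")) {
  if (cfg$grouping != "cell") cfg$grouping <- "cell"
  design <- build_design(table, lag)
  lambda <- cfg$lambda %||% cv_lambda(design, cfg)$lambda
  fold <- assign_folds(design, cfg)
  rfs <- lapply(seq_len(cfg$folds), function(f) {
    sel <- fold != f
    sub <- list(X = design$X[sel, , drop = FALSE], y = design$y[sel],
                index = design$index[sel, , drop = FALSE])
    attributes(sub)[c("axis", "lag")] <- attributes(design)[c("axis", "lag")]
    ridge_fit(sub, lambda, standardize = cfg$standardize)
  })
  V <- vapply(rfs, flatten_rf, numeric(length(flatten_rf(rfs[[1L]]))))
  k <- length(rfs)
  S <- matrix(1, k, k)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
    S[i, j] <- S[j, i] <- cosine_similarity(V[, i], V[, j])
  list(rfs = rfs, similarity = S, lambda = lambda)
}

#' Predict accelerations from a fitted response function
#'
#' @param rf A response function.
#' @param table A feature table assembled for the same axis.
#' @return Data frame `cell_id`, `frame`, `observed`, `predicted` for every
#'   row with full lag history.
#' @export
predict_acceleration <- function(rf, table) {
  table_axis <- attr(table, "axis") %||% unique(table$axis)[1L]
  if (!is.null(table_axis) && !is.na(table_axis) && table_axis != rf$axis)
    stop(sprintf("axis mismatch: model is '%s', table is '%s'",
                 rf$axis, table_axis))
  design <- build_design(table, rf$lag)
  data.frame(design$index,
             observed = design$y,
             predicted = drop(design$X %*% rf_theta(rf)),
             stringsAsFactors = FALSE)
}

#' Cosine similarity of two vectors
#'
#' `a . b / (||a|| ||b||)`, in `[-1, 1]`. Undefined for a zero vector, in
#' which case `NA` is returned with a warning.
#'
#' @param a,b Numeric vectors of equal length.
#' @return A scalar.
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    warning("cosine similarity undefined for a zero vector")
    return(NA_real_)
  }
  sum(a * b) / (na * nb)
}
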