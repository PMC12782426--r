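#' Fit a response function for every cell
#'
#' One ridge fit per cell at the supplied lambda (the population-level lambda
#' by default reuse; pass a per-cell CV result if preferred). Cells with
#' fewer than `L` usable frames are excluded with a reason rather than
#' fitted.
#'
#' @param table A feature table.
#' @param lag A [lag_spec()].
#' @param lambda Ridge strength shared by all per-cell fits.
#' @param standardize Passed to [ridge_fit()].
#' @return A list with class `cell_rf_set`: `rfs` (named list of response
#'   functions), `excluded` (named character of reasons) and `lambda`.
#' @export
fit_per_cell <- function(table, lag = lag_spec(), lambda, standardize = FALSE) {
  stop_if_not_scalar_num(lambda, "lambda", positive = TRUE)
  rfs <- list()
  excluded <- character(0)
  for (sub in split(table, table$cell_id)) {
    cid <- sub$cell_id[1L]
    if (nrow(sub) < lag$L) {
      excluded[cid] <- sprintf("only %d frames (< L = %d)", nrow(sub), lag$L)
      next
    }
    attr(sub, "axis") <- attr(table, "axis") %||% sub$axis[1L]
    design <- build_design(sub, lag)
    rfs[[cid]] <- ridge_fit(design, lambda, standardize = standardize)
  }
  structure(list(rfs = rfs, excluded = excluded, lambda = lambda),
            class = "cell_rf_set")
}

#' @export
print.cell_rf_set <- function(x, ...) {
  cat(sprintf("Per-cell response functions: %d cells fitted at lambda = %g",
              length(x$rfs), x$lambda))
  if (length(x$excluded))
    cat(sprintf(", %d excluded", length(x$excluded)))
  cat("\n")
  invisible(x)
}

#' Rank cells by how well the population model predicts them
#'
#' Scores each cell by the Pearson correlation between its observed and
#' predicted accelerations under the population-level response function and
#' sorts in descending order. A cell whose observed acceleration is constant
#' has an undefined correlation; it is scored as missing and ranked last.
#' Ties break by cell id.
#'
#' @param population_rf The population-level response function.
#' @param table The (test) feature table.
#' @return Data frame `cell_id`, `score`, `rank` in rank order.
#' @export
rank_cells <- function(population_rf, table) {
  pred <- predict_acceleration(population_rf, table)
  score <- vapply(split(pred, pred$cell_id), function(s) {
    if (stats::sd(s$observed) == 0 || stats::sd(s$predicted) == 0)
      return(NA_real_)
    stats::cor(s$observed, s$predicted)
  }, numeric(1L))
  ord <- order(-score, names(score), na.last = TRUE)
  data.frame(cell_id = names(score)[ord], score = unname(score[ord]),
             rank = seq_along(score), stringsAsFactors = FALSE)
}

#' Pairwise cosine-similarity matrix of per-cell response functions
#'
#' Entries are the cosine similarity of the flattened, concatenated kernel
#' vectors ([flatten_rf()]); the diagonal is 1. Rows and columns follow the
#' supplied ordering (typically the prediction ranking), so well-predicted
#' cells cluster toward the upper left.
#'
#' @param rf_set A [fit_per_cell()] result.
#' @param order Optional character vector of cell ids giving the row order.
#' @param include_bias,include_velocity Passed to [flatten_rf()].
#' @return Symmetric numeric matrix with unit diagonal.
#' @export
similarity_matrix <- function(rf_set, order = NULL,
                              include_bias = FALSE, include_velocity = TRUE) {
  rfs <- rf_set$rfs
  if (length(rfs) < 2L) stop("need at least 2 per-cell response functions")
  if (!is.null(order)) {
    order <- intersect(order, names(rfs))
    rfs <- rfs[order]
  }
  V <- vapply(rfs, flatten_rf, include_bias = include_bias,
              include_velocity = include_velocity,
              numeric(length(flatten_rf(rfs[[1L]], include_bias,
                                        include_velocity))))
  nrm <- sqrt(colSums(V^2))
  if (any(nrm == 0)) warning("zero-norm response function in similarity matrix")
  Vn <- sweep(V, 2L, ifelse(nrm == 0, 1, nrm), `/`)
  S <- crossprod(Vn)
  diag(S) <- 1
  S
}

#' Principal-component analysis of per-cell response functions
#'
#' PCA of the mean-centred flattened response-function vectors (no
#' per-feature scaling). Explained-variance fractions sum to 1.
#'
#' @param rf_set A [fit_per_cell()] result with at least 3 cells.
#' @param include_bias,include_velocity Passed to [flatten_rf()].
#' @return List with `scores` (cells x components), `explained`
#'   (variance fractions), `rotation` and `center`.
#' @export
pca_response_functions <- function(rf_set, include_bias = FALSE,
                                   include_velocity = TRUE) {
  rfs <- rf_set$rfs
  if (length(rfs) < 3L) stop("need at least 3 per-cell response functions")
  V <- t(vapply(rfs, flatten_rf, include_bias = include_bias,
                include_velocity = include_velocity,
                numeric(length(flatten_rf(rfs[[1L]], include_bias,
                                          include_velocity)))))
  pr <- stats::prcomp(V, center = TRUE, scale. = FALSE)
  list(scores = pr$x, explained = pr$sdev^2 / sum(pr$sdev^2),
       rotation = pr$rotation, center = pr$center)
}

#' Mean response functions of the best- and worst-predicted subgroups
#'
#' Averages the per-cell response functions of the `n_best` top-ranked and
#' `n_worst` bottom-ranked cells (by [rank_cells()] order).
#'
#' @param rf_set A [fit_per_cell()] result.
#' @param ranking Output of [rank_cells()].
#' @param n_best,n_worst Subgroup sizes (default 20 each).
#' @return List with response functions `best` and `worst`.
#' @export
subgroup_mean_rf <- function(rf_set, ranking, n_best = 20L, n_worst = 20L) {
  ids <- ranking$cell_id[ranking$cell_id %in% names(rf_set$rfs)]
  if (n_best + n_worst > length(ids))
    stop(sprintf("n_best + n_worst = %d exceeds the %d ranked, fitted cells",
                 n_best + n_worst, length(ids)))
  best_ids <- utils::head(ids, n_best)
  worst_ids <- utils::tail(ids, n_worst)
  list(best = mean_response_function(rf_set$rfs[best_ids]),
       worst = mean_response_function(rf_set$rfs[worst_ids]))
}
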