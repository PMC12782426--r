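#' Tracked-cell tables
#'
#' A track table holds one row per cell per frame with the columns
#' `cell_id`, `frame`, `x_px`, `y_px` (positions in pixels; x is the axis
#' orthogonal to the wound, y parallel) and `erk` (FRET/CFP ratio at the cell
#' centroid). Frames are imaged at a fixed interval (2 min by default).
#' Missing measurements are encoded as `NA`; [filter_trajectories()] discards
#' tracks containing any.
#'
#' @param df A data frame with the track-table columns.
#' @return `df`, ordered by cell then frame, with class `track_table`.
#' @export
as_track_table <- function(df) {
  required <- c("cell_id", "frame", "x_px", "y_px", "erk")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("track table is missing columns: ", paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df)[required]
  df$cell_id <- as.character(df$cell_id)
  df$frame <- as.integer(df$frame)
  df <- df[order(df$cell_id, df$frame), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("track_table", "data.frame")
  df
}

#' Read a tracked-cell table from delimited text
#'
#' @param path File path. The file must have a header row with columns
#'   `cell_id`, `frame`, `x_px`, `y_px`, `erk`; empty fields are read as
#'   missing values.
#' @param sep Field separator (default tab).
#' @return A [as_track_table()] data frame.
#' @export
read_track_table <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("track table file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = c("", "NA"), stringsAsFactors = FALSE)
  as_track_table(df)
}

#' @rdname read_track_table
#' @param tracks A track table.
#' @export
write_track_table <- function(tracks, path, sep = "\t") {
  utils::write.table(tracks, path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Filter trajectories for regression use
#'
#' Keeps only tracks that span at least `min_frames` frames, contain no
#' missing values and have gap-free (unit-step) frame indices; optionally the
#' track must also begin at the dataset's first frame. Removal reasons are
#' attached as the `"removed"` attribute.
#'
#' @param tracks A track table.
#' @param min_frames Minimum track length in frames (default 400).
#' @param require_first_frame If `TRUE`, drop tracks that do not start at the
#'   dataset's first frame.
#' @return The filtered track table (possibly empty), with attribute
#'   `removed`: a data frame of `cell_id` and `reason`.
#' @export
filter_trajectories <- function(tracks, min_frames = 400L,
                                require_first_frame = FALSE) {
  stop_if_not_scalar_num(min_frames, "min_frames", positive = TRUE, integer = TRUE)
  tracks <- as_track_table(tracks)
  first_frame <- if (nrow(tracks)) min(tracks$frame) else NA_integer_
  per_cell <- split(seq_len(nrow(tracks)), tracks$cell_id)
  removed <- list()
  keep <- logical(nrow(tracks))
  for (cid in names(per_cell)) {
    idx <- per_cell[[cid]]
    sub <- tracks[idx, ]
    reason <- NULL
    if (anyNA(sub[c("x_px", "y_px", "erk")])) reason <- "missing_values"
    else if (nrow(sub) < min_frames) reason <- "too_short"
    else if (nrow(sub) > 1L && any(diff(sub$frame) != 1L)) reason <- "frame_gap"
    else if (require_first_frame && sub$frame[1L] != first_frame) reason <- "late_start"
    if (is.null(reason)) keep[idx] <- TRUE else removed[[cid]] <- reason
  }
  out <- tracks[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("track_table", "data.frame")
  attr(out, "removed") <- data.frame(
    cell_id = names(removed),
    reason = unlist(removed, use.names = FALSE) %||% character(0),
    stringsAsFactors = FALSE
  )
  out
}
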