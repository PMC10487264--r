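#' @title Detection tables
#' @description
#' Throughout the package per-frame bounding-box detections travel as a single
#' data frame with one row per detection and columns:
#' \describe{
#'   \item{frame}{0-based integer frame index (MOT files are 1-based on disk;
#'     the shift happens at the I/O boundary).}
#'   \item{x, y}{pixel coordinates of the box's left and top edge (minimum
#'     corner, image origin at top-left).}
#'   \item{w, h}{box width and height in pixels, strictly positive.}
#'   \item{conf}{detection confidence in [0, 1].}
#' }
#' Simulated detections carry an extra \code{truth_id} column (the generating
#' bird's ID, -1 for false positives). \code{\link{split_frames}} regroups the
#' table into a per-frame list when an algorithm consumes frames one at a time.
#' @name detection-tables
#' @keywords internal
NULL

empty_detections <- function(truth = FALSE) {
  d <- data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                  w = numeric(0), h = numeric(0), conf = numeric(0))
  if (truth) d$truth_id <- integer(0)
  d
}

#' Read detections in MOT-Challenge CSV dialect
#'
#' Parses the comma-separated \code{frame,id,x,y,w,h,conf,...} detection
#' dialect. The \code{id} field is ignored for detection files (detectors
#' write -1). Frames are converted from the file's 1-based indexing to the
#' package's 0-based indexing and rows are returned in ascending frame order.
#' Rows with non-positive width or height are skipped; the number skipped is
#' attached as attribute \code{n_rejected} and reported once as a warning.
#'
#' @param path Path to the CSV file. An empty file yields an empty table.
#' @return A detection data frame (see \link{detection-tables}) with
#'   attribute \code{n_rejected}.
#' @export
read_mot_detections <- function(path) {
  if (!file.exists(path)) stop("detection file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    out <- empty_detections()
    attr(out, "n_rejected") <- 0L
    return(out)
  }
  parts <- strsplit(lines, ",", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 7)) {
    stop("malformed row (fewer than 7 comma-separated fields) at line ",
         which(nf < 7)[1])
  }
  num <- matrix(NA_real_, nrow = length(parts), ncol = 7)
  for (j in 1:7) num[, j] <- suppressWarnings(
    as.numeric(vapply(parts, `[[`, character(1), j)))
  bad <- which(!stats::complete.cases(num))
  if (length(bad)) {
    stop("malformed row (non-numeric field) at line ", bad[1])
  }
  keep <- num[, 5] > 0 & num[, 6] > 0
  n_rejected <- sum(!keep)
  if (n_rejected > 0) {
    warning(n_rejected, " row(s) with non-positive box size skipped")
  }
  num <- num[keep, , drop = FALSE]
  out <- data.frame(frame = as.integer(num[, 1]) - 1L,
                    x = num[, 3], y = num[, 4],
                    w = num[, 5], h = num[, 6],
                    conf = num[, 7])
  out <- out[order(out$frame), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Read YOLO-format normalized label files
#'
#' Each frame is one whitespace-separated text file of
#' \code{class cx cy w h} rows with all geometry normalized to [0, 1]; the
#' frame index is the trailing integer in the file name
#' (e.g. \code{frame_000017.txt} is frame 17). Boxes are converted to pixel
#' minimum-corner form: \code{x = (cx - w/2) * image_width_px} and likewise
#' for y. Rows with normalized values outside [0, 1], or whose converted
#' corner falls outside the image, are rejected with a counted warning
#' (set \code{clamp = TRUE} to clamp such corners to the image instead).
#'
#' @param directory Directory containing \code{.txt} label files.
#' @param image_width_px,image_height_px Image dimensions in pixels.
#' @param clamp Clamp out-of-image corners to the image bounds instead of
#'   rejecting the row (default FALSE).
#' @return A detection data frame (confidence 1 for all rows, as label files
#'   carry none) with attribute \code{n_rejected}.
#' @export
read_yolo_labels <- function(directory, image_width_px, image_height_px,
                             clamp = FALSE) {
  if (!dir.exists(directory)) stop("label directory not found: ", directory)
  stopifnot(image_width_px > 0, image_height_px > 0)
  files <- list.files(directory, pattern = "\\.txt$", full.names = TRUE)
  rows <- list()
  n_rejected <- 0L
  for (f in files) {
    stem <- sub("\\.txt$", "", basename(f))
    m <- regmatches(stem, regexpr("[0-9]+$", stem))
    if (!length(m)) stop("cannot parse frame index from file name: ",
                         basename(f))
    frame <- as.integer(m)
    lines <- readLines(f, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) next
    vals <- lapply(strsplit(trimws(lines), "[[:space:]]+"), as.numeric)
    for (i in seq_along(vals)) {
      v <- vals[[i]]
      if (length(v) < 5 || anyNA(v)) {
        stop("malformed label row at ", basename(f), " line ", i)
      }
      cx <- v[2]; cy <- v[3]; w <- v[4]; h <- v[5]
      if (any(c(cx, cy, w, h) < 0) || any(c(cx, cy, w, h) > 1) ||
          w == 0 || h == 0) {
        n_rejected <- n_rejected + 1L
        next
      }
      x <- (cx - w / 2) * image_width_px
      y <- (cy - h / 2) * image_height_px
      wp <- w * image_width_px
      hp <- h * image_height_px
      if (x < 0 || y < 0 || x + wp > image_width_px ||
          y + hp > image_height_px) {
        if (clamp) {
          x <- min(max(x, 0), image_width_px - wp)
          y <- min(max(y, 0), image_height_px - hp)
        } else {
          n_rejected <- n_rejected + 1L
          next
        }
      }
      rows[[length(rows) + 1L]] <- c(frame, x, y, wp, hp)
    }
  }
  if (n_rejected > 0) {
    warning(n_rejected, " label row(s) outside the unit square or image skipped")
  }
  if (!length(rows)) {
    out <- empty_detections()
  } else {
    m <- do.call(rbind, rows)
    out <- data.frame(frame = as.integer(m[, 1]), x = m[, 2], y = m[, 3],
                      w = m[, 4], h = m[, 5], conf = 1)
    out <- out[order(out$frame), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Write trajectories in MOT-Challenge ground-truth dialect
#'
#' Writes one \code{frame,id,x,y,w,h,1,1,1} row per observation, with the
#' centroid converted back to the box's minimum corner and frames shifted to
#' the dialect's 1-based indexing. Reading the file back with
#' \code{\link{read_mot_detections}} reproduces the (frame, id, box) triples
#' bit-exactly for integer-pixel boxes.
#'
#' @param trajectories A list of trajectory objects (see
#'   \code{\link{merge_tracklets}}) with pixel-space boxes.
#' @param path Output file path.
#' @return The number of rows written, invisibly.
#' @export
write_mot_tracks <- function(trajectories, path) {
  rows <- character(0)
  for (tr in trajectories) {
    if (!length(tr$frames)) next
    rows <- c(rows, sprintf("%d,%d,%s,%s,%s,%s,1,1,1",
                            tr$frames + 1L, tr$bird_id,
                            format(tr$cx - tr$w / 2, digits = 15, trim = TRUE,
                                   scientific = FALSE),
                            format(tr$cy - tr$h / 2, digits = 15, trim = TRUE,
                                   scientific = FALSE),
                            format(tr$w, digits = 15, trim = TRUE,
                                   scientific = FALSE),
                            format(tr$h, digits = 15, trim = TRUE,
                                   scientific = FALSE)))
  }
  ok <- tryCatch({ writeLines(rows, path); TRUE },
                 error = function(e) stop("cannot write ", path, ": ",
                                          conditionMessage(e)))
  invisible(length(rows))
}

#' Read tracks written in MOT ground-truth dialect
#'
#' Companion reader for \code{\link{write_mot_tracks}}: like
#' \code{\link{read_mot_detections}} but the \code{id} column is retained and
#' rows are grouped into per-ID trajectory objects.
#'
#' @param path Path to the CSV file.
#' @return A list of trajectory objects sorted by ID.
#' @export
read_mot_tracks <- function(path) {
  if (!file.exists(path)) stop("track file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(list())
  parts <- strsplit(lines, ",", fixed = TRUE)
  if (any(lengths(parts) < 6)) {
    stop("malformed row at line ", which(lengths(parts) < 6)[1])
  }
  num <- matrix(NA_real_, nrow = length(parts), ncol = 6)
  for (j in 1:6) num[, j] <- suppressWarnings(
    as.numeric(vapply(parts, `[[`, character(1), j)))
  if (anyNA(num)) stop("malformed row at line ", which(!stats::complete.cases(num))[1])
  df <- data.frame(frame = as.integer(num[, 1]) - 1L, id = as.integer(num[, 2]),
                   x = num[, 3], y = num[, 4], w = num[, 5], h = num[, 6])
  lapply(split(df, df$id), function(g) {
    g <- g[order(g$frame), , drop = FALSE]
    new_trajectory(bird_id = g$id[1], frames = g$frame,
                   cx = g$x + g$w / 2, cy = g$y + g$h / 2,
                   w = g$w, h = g$h, source_ids = g$id[1])
  })
}

#' Split a detection table into per-frame groups
#'
#' @param dets A detection data frame.
#' @return A named list of data frames, one per frame present, in ascending
#'   frame order.
#' @export
split_frames <- function(dets) {
  if (!nrow(dets)) return(list())
  split(dets, factor(dets$frame, levels = sort(unique(dets$frame))))
}
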