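#' Intersection over union of two box sets (vectorized)
#'
#' @param a,b Data frames or lists with fields \code{x}, \code{y}, \code{w},
#'   \code{h}; recycled elementwise.
#' @return Numeric vector of IoU values in [0, 1].
#' @export
box_iou <- function(a, b) {
  ix <- pmax(0, pmin(a$x + a$w, b$x + b$w) - pmax(a$x, b$x))
  iy <- pmax(0, pmin(a$y + a$h, b$y + b$h) - pmax(a$y, b$y))
  inter <- ix * iy
  union <- a$w * a$h + b$w * b$h - inter
  ifelse(union > 0, inter / union, 0)
}

# ground-truth tracks -> pixel boxes of the simulator's nominal size
truth_boxes <- function(truth, calib, bird_radius_cm) {
  if (!nrow(truth)) {
    return(data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      w = numeric(0), h = numeric(0)))
  }
  w <- 2 * bird_radius_cm / calib$cm_per_px_x
  h <- 2 * bird_radius_cm / calib$cm_per_px_y
  data.frame(frame = truth$frame,
             x = truth$x_cm / calib$cm_per_px_x - w / 2,
             y = truth$y_cm / calib$cm_per_px_y - h / 2,
             w = w, h = h)
}

#' Match detections to ground truth at an IoU threshold
#'
#' Greedy confidence-descending matching per frame: each detection, in
#' decreasing confidence order, claims the not-yet-matched ground-truth box
#' with the highest IoU, provided that IoU reaches the threshold; otherwise
#' it is a false positive. Ground-truth boxes left unclaimed are false
#' negatives.
#'
#' @param dets A detection data frame.
#' @param truth Ground-truth tracks (\code{\link{simulate_motion}} output).
#' @param calib A \code{\link{calibrate_pen}} object.
#' @param iou_threshold IoU threshold (default 0.5).
#' @param bird_radius_cm Nominal body radius used to render truth boxes.
#' @return An object of class \code{detection_match}: counts \code{tp},
#'   \code{fp}, \code{fn} and the threshold.
#' @export
match_detections <- function(dets, truth, calib, iou_threshold = 0.5,
                             bird_radius_cm = 6) {
  tb <- truth_boxes(truth, calib, bird_radius_cm)
  flags <- match_flags(dets, tb, iou_threshold)
  structure(list(tp = sum(flags$tp), fp = sum(!flags$tp),
                 fn = nrow(tb) - sum(flags$tp),
                 iou_threshold = iou_threshold),
            class = "detection_match")
}

# per-detection TP/FP flags in global confidence-descending order,
# with per-frame one-to-one claiming of truth boxes
match_flags <- function(dets, tb, iou_threshold) {
  if (!nrow(dets)) {
    return(list(order = integer(0), tp = logical(0), conf = numeric(0)))
  }
  ord <- order(-dets$conf, dets$frame)
  tb_by_frame <- split(seq_len(nrow(tb)), tb$frame)
  claimed <- rep(FALSE, nrow(tb))
  tp <- logical(length(ord))
  for (k in seq_along(ord)) {
    i <- ord[k]
    cand <- tb_by_frame[[as.character(dets$frame[i])]]
    cand <- cand[!claimed[cand]]
    if (!length(cand)) next
    ious <- box_iou(dets[i, ], tb[cand, ])
    best <- which.max(ious)
    if (ious[best] >= iou_threshold) {
      claimed[cand[best]] <- TRUE
      tp[k] <- TRUE
    }
  }
  list(order = ord, tp = tp, conf = dets$conf[ord])
}

#' @export
print.detection_match <- function(x, ...) {
  cat(sprintf("Detection match @ IoU %.2f: TP %d, FP %d, FN %d\n",
              x$iou_threshold, x$tp, x$fp, x$fn))
  invisible(x)
}

#' Detection precision
#'
#' \code{TP / (TP + FP)}; defined as 1 when there are no predictions at all.
#'
#' @param result A \code{\link{match_detections}} result.
#' @return Precision in [0, 1].
#' @export
detection_precision <- function(result) {
  denom <- result$tp + result$fp
  if (denom == 0) return(1.0)
  result$tp / denom
}

#' Average precision (and mAP) over a confidence sweep
#'
#' Ranks all detections by confidence, accumulates precision and recall,
#' and integrates the precision envelope over recall (all-point
#' interpolation). With a single object class the mean average precision
#' equals the AP itself.
#'
#' @inheritParams match_detections
#' @return A list with \code{ap} and \code{map} (equal for one class).
#' @export
average_precision <- function(dets, truth, calib, iou_threshold = 0.5,
                              bird_radius_cm = 6) {
  tb <- truth_boxes(truth, calib, bird_radius_cm)
  if (!nrow(tb)) stop("average precision is undefined with empty ground truth")
  flags <- match_flags(dets, tb, iou_threshold)
  if (!length(flags$tp)) return(list(ap = 0, map = 0))
  cum_tp <- cumsum(flags$tp)
  cum_fp <- cumsum(!flags$tp)
  recall <- cum_tp / nrow(tb)
  prec <- cum_tp / (cum_tp + cum_fp)
  # precision envelope (running max from the right), integrated over recall
  env <- rev(cummax(rev(prec)))
  r_prev <- c(0, recall[-length(recall)])
  ap <- sum((recall - r_prev) * env)
  list(ap = ap, map = ap)
}

#' Coefficient of determination
#'
#' Standard squared-residual form
#' \code{1 - sum((y - yhat)^2) / sum((y - mean(y))^2)}.
#'
#' @param actual Observed values (not all equal; length >= 2).
#' @param predicted Predicted values of the same length.
#' @return R squared (at most 1; can be negative for poor predictions).
#' @export
r_squared <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    stop("actual and predicted must have equal length")
  }
  if (length(actual) < 2) stop("need at least two observations")
  ss_tot <- sum((actual - mean(actual))^2)
  if (ss_tot == 0) stop("R squared is undefined for constant actual values")
  1 - sum((actual - predicted)^2) / ss_tot
}

# majority ground-truth bird id of a tracklet/trajectory via its detection rows
majority_truth_id <- function(det_rows, truth_ids) {
  rows <- det_rows[!is.na(det_rows)]
  if (!length(rows)) return(NA_integer_)
  tab <- table(truth_ids[rows])
  as.integer(names(tab)[which.max(tab)])
}

#' Score ID re-association against simulator truth
#'
#' A merge is correct when the two tracklets it joins have the same
#' (non-clutter) majority ground-truth bird. Merge accuracy is the share of
#' correct merges among attempted ones (vacuously 1 when none were
#' attempted). When ground-truth tracks are supplied, the per-bird relative
#' distance error of the recovered trajectories is also computed:
#' \code{|recovered - truth| / truth} averaged over birds, as a percentage,
#' with the truth distance measured on the same sampling grid and deadband
#' as the recovered one.
#'
#' @param trajectories Merged trajectories from \code{\link{merge_tracklets}}
#'   (built from tracklets carrying \code{det_rows}).
#' @param tracklets The tracklets that were merged.
#' @param truth_ids The detection table's \code{truth_id} column.
#' @param truth Optional ground-truth tracks for the distance error.
#' @param calib,config Required with \code{truth}: calibration and run
#'   configuration used by the mobility stage.
#' @return A list: \code{merge_accuracy}, \code{n_merges},
#'   \code{distance_error_pct} (mean over birds) and
#'   \code{distance_error_max_pct} (worst bird); the error entries are NA
#'   without \code{truth}.
#' @export
id_recovery_metrics <- function(trajectories, tracklets, truth_ids,
                                truth = NULL, calib = NULL, config = NULL) {
  maj <- vapply(tracklets, function(tk) majority_truth_id(tk$det_rows,
                                                          truth_ids),
                integer(1))
  names(maj) <- vapply(tracklets, `[[`, integer(1), "track_id")
  n_merges <- 0L
  n_correct <- 0L
  for (tr in trajectories) {
    src <- as.character(tr$source_ids)
    if (length(src) < 2) next
    for (k in 2:length(src)) {
      n_merges <- n_merges + 1L
      a <- maj[[src[k - 1]]]; b <- maj[[src[k]]]
      if (!is.na(a) && !is.na(b) && a == b && a != -1L) {
        n_correct <- n_correct + 1L
      }
    }
  }
  acc <- if (n_merges == 0) 1.0 else n_correct / n_merges
  err <- err_max <- NA_real_
  if (!is.null(truth)) {
    stopifnot(!is.null(calib), !is.null(config))
    total_frames <- max(truth$frame) + 1L
    rec <- numeric(0)
    for (tr in trajectories) {
      bird <- majority_truth_id(tr$det_rows, truth_ids)
      if (is.na(bird) || bird == -1L) next
      s <- bird_summary(tr, calib, config, total_frames)
      rec[as.character(bird)] <-
        sum(rec[as.character(bird)], s$total_distance, na.rm = TRUE)
    }
    errs <- vapply(names(rec), function(b) {
      g <- truth[truth$bird_id == as.integer(b), ]
      g <- g[order(g$frame), ]
      gt <- new_trajectory(as.integer(b), g$frame,
                           g$x_cm / calib$cm_per_px_x,
                           g$y_cm / calib$cm_per_px_y)
      gp <- resample_trajectory(gt, config$sample_interval, config$frame_rate)
      gd <- sum(displacement_series(gp, calib, config$deadband))
      if (gd > 0) abs(rec[[b]] - gd) / gd * 100 else NA_real_
    }, numeric(1))
    err <- mean(errs, na.rm = TRUE)
    err_max <- if (all(is.na(errs))) NA_real_ else max(errs, na.rm = TRUE)
  }
  list(merge_accuracy = acc, n_merges = n_merges,
       distance_error_pct = err, distance_error_max_pct = err_max)
}
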