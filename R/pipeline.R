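#' Track a pen and quantify per-bird mobility
#'
#' The full pipeline on one recording: run the kinematic tracker over the
#' detection stream, repair occlusion-induced ID switches by matching lost
#' IDs with newly born IDs under the configured distance threshold, delete
#' false-detection tracks, merge the survivors into bird-level trajectories,
#' and summarize per-bird and flock-level distance (cm), speed (cm/s) and
#' appearance percentage. Re-association distances are measured in cm
#' (event positions are converted through the pen calibration before
#' thresholding), so the threshold is independent of image resolution.
#'
#' @param dets A detection data frame (see \link{detection-tables}).
#' @param config A \code{\link{run_config}}.
#' @param params A \code{\link{tracker_params}}; by default the gate
#'   distance is set to half the median detection box width (one body
#'   radius). Per-frame bird displacement is a small fraction of the body,
#'   so a tight gate keeps tracks from being captured by clutter or
#'   neighbours while their bird is occluded; re-association, not a wide
#'   gate, is the mechanism for surviving long gaps.
#' @param n_frames Number of frames in the recording; defaults to
#'   \code{max(dets$frame) + 1}.
#' @param period Optional period label carried into the summaries.
#' @return An object of class \code{pen_tracking}: \code{tracklets},
#'   \code{events}, \code{mapping}, \code{trajectories} (px),
#'   \code{per_bird} and \code{flock} summary data frames, plus the
#'   \code{config}, \code{calib} and \code{params} used.
#' @export
#' @examples
#' cfg <- run_config(frame_rate = 5, image_width_px = 500,
#'                   image_height_px = 750)
#' sim <- sim_config(n_birds = 3, duration_s = 60, seed = 7)
#' calib <- calibrate_pen(100, 150, 500, 750)
#' truth <- simulate_motion(sim)
#' dets <- render_detections(truth, no_noise(), calib, seed = 7)
#' fit <- track_pen(dets, cfg)
#' summary(fit)
track_pen <- function(dets, config = run_config(), params = NULL,
                      n_frames = NULL, period = NA_character_) {
  calib <- calibration_from_config(config)
  if (is.null(n_frames)) {
    n_frames <- if (nrow(dets)) max(dets$frame) + 1L else 0L
  }
  if (is.null(params)) {
    gate <- if (nrow(dets)) 0.5 * stats::median(dets$w) else 150
    params <- tracker_params(gate_distance = gate)
  }
  tracklets <- run_tracker(dets, params, n_frames)
  ev <- find_events(tracklets, video_end = n_frames - 1L,
                    spawn_window = params$min_hits)
  # threshold in cm: convert event positions px -> cm before matching
  losses_cm <- ev$losses
  births_cm <- ev$births
  losses_cm$x <- losses_cm$x * calib$cm_per_px_x
  losses_cm$y <- losses_cm$y * calib$cm_per_px_y
  births_cm$x <- births_cm$x * calib$cm_per_px_x
  births_cm$y <- births_cm$y * calib$cm_per_px_y
  mapping <- match_lost_new(losses_cm, births_cm,
                            distance_threshold = config$distance_threshold,
                            max_gap = config$max_gap,
                            min_track_length = config$min_track_length)
  trajectories <- merge_tracklets(tracklets, mapping)
  per_bird <- do.call(rbind, lapply(trajectories, bird_summary,
                                    calib = calib, config = config,
                                    total_frames = n_frames,
                                    period = period))
  flock <- if (!is.null(per_bird) && nrow(per_bird)) {
    flock_summary(per_bird, period)
  } else NULL
  structure(list(tracklets = tracklets, events = ev, mapping = mapping,
                 trajectories = trajectories, per_bird = per_bird,
                 flock = flock, config = config, calib = calib,
                 params = params, n_frames = n_frames),
            class = "pen_tracking")
}

#' @export
print.pen_tracking <- function(x, ...) {
  cat("Pen tracking result\n")
  cat(sprintf("  frames: %d, tracklets: %d, trajectories (birds): %d\n",
              x$n_frames, length(x$tracklets), length(x$trajectories)))
  cat(sprintf("  ID repairs: %d merge(s), %d deletion(s), %d unresolved\n",
              nrow(x$mapping$merges), length(x$mapping$deletions),
              length(x$mapping$unresolved)))
  if (!is.null(x$flock)) {
    cat(sprintf("  flock: %.1f cm moved on average (SD %.1f), mean speed %.2f cm/s\n",
                x$flock$mean_distance,
                if (is.na(x$flock$sd_distance)) 0 else x$flock$sd_distance,
                x$flock$mean_speed))
  }
  invisible(x)
}

#' @export
summary.pen_tracking <- function(object, ...) {
  print(object)
  if (!is.null(object$per_bird)) {
    cat("\nPer-bird mobility:\n")
    pb <- object$per_bird
    pb$total_distance <- round(pb$total_distance, 1)
    pb$mean_speed <- round(pb$mean_speed, 3)
    pb$appearance_pct <- round(pb$appearance_pct, 1)
    print(pb, row.names = FALSE)
  }
  invisible(object$per_bird)
}

#' Plot merged trajectories in pen coordinates
#'
#' @param x A \code{pen_tracking} object.
#' @param ... Passed to \code{\link[graphics]{plot}}.
#' @export
plot.pen_tracking <- function(x, ...) {
  cal <- x$calib
  graphics::plot(NA, xlim = c(0, x$config$pen_width_cm),
                 ylim = c(x$config$pen_height_cm, 0),
                 xlab = "x (cm)", ylab = "y (cm)",
                 main = "Merged bird trajectories", asp = 1, ...)
  cols <- grDevices::hcl.colors(max(1L, length(x$trajectories)), "Dark 3")
  for (i in seq_along(x$trajectories)) {
    tr <- x$trajectories[[i]]
    graphics::lines(tr$cx * cal$cm_per_px_x, tr$cy * cal$cm_per_px_y,
                    col = cols[i])
  }
  invisible(x)
}
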