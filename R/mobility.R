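#' Bounding-box centroid
#'
#' The centroid of a minimum-corner box: \code{xc = x + w/2},
#' \code{yc = y + h/2}. Accepts vectors, so a whole detection table's
#' centroids come back in one call.
#'
#' @param x,y Left and top edge in px.
#' @param w,h Box width and height in px.
#' @return A list with numeric components \code{xc} and \code{yc}.
#' @export
#' @examples
#' box_centroid(10, 20, 4, 6)  # (12, 23)
box_centroid <- function(x, y, w, h) {
  list(xc = x + w / 2, yc = y + h / 2)
}

#' Pixel-to-cm pen calibration
#'
#' Linear anisotropic scaling under a nadir-view assumption: the pen fills
#' the frame, so \code{cm_per_px_x = pen_w_cm / image_w_px} and likewise in
#' y. The two axes are calibrated separately because the pen need not be
#' square in the frame. No lens-distortion model is applied.
#'
#' @param pen_w_cm,pen_h_cm Pen dimensions in cm.
#' @param image_w_px,image_h_px Image dimensions in px.
#' @return An object of class \code{pen_calibration} with fields
#'   \code{cm_per_px_x} and \code{cm_per_px_y}.
#' @export
#' @examples
#' calibrate_pen(100, 150, 2592, 1944)
calibrate_pen <- function(pen_w_cm, pen_h_cm, image_w_px, image_h_px) {
  vals <- c(pen_w_cm, pen_h_cm, image_w_px, image_h_px)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("calibration inputs must be positive")
  }
  structure(list(cm_per_px_x = pen_w_cm / image_w_px,
                 cm_per_px_y = pen_h_cm / image_h_px),
            class = "pen_calibration")
}

#' @export
print.pen_calibration <- function(x, ...) {
  cat(sprintf("Pen calibration: %.5f cm/px (x), %.5f cm/px (y)\n",
              x$cm_per_px_x, x$cm_per_px_y))
  invisible(x)
}

calibration_from_config <- function(config) {
  calibrate_pen(config$pen_width_cm, config$pen_height_cm,
                config$image_width_px, config$image_height_px)
}

#' Resample a trajectory onto a fixed time grid
#'
#' Keeps, for each grid time \code{t = 0, interval, 2*interval, ...}, the
#' observation nearest to it (within half an interval; ties resolved to the
#' earlier frame). Grid points with no observation nearby are simply absent:
#' gaps propagate to the displacement series as skipped segments and are
#' never interpolated, so hidden birds do not accrue fictitious distance.
#'
#' @param traj A trajectory object (fields \code{frames}, \code{cx},
#'   \code{cy} in px; see \code{\link{merge_tracklets}}).
#' @param interval_s Grid interval in seconds.
#' @param frame_rate Frames per second.
#' @return A data frame with columns \code{grid} (integer grid index),
#'   \code{time_s}, \code{x}, \code{y} (px), sorted by grid index.
#' @export
resample_trajectory <- function(traj, interval_s, frame_rate) {
  stopifnot(interval_s > 0, frame_rate > 0)
  if (interval_s * frame_rate < 1) {
    stop("interval_s * frame_rate must be >= 1")
  }
  n <- length(traj$frames)
  if (!n) {
    return(data.frame(grid = integer(0), time_s = numeric(0),
                      x = numeric(0), y = numeric(0)))
  }
  t <- traj$frames / frame_rate
  g <- as.integer(round(t / interval_s))
  # the grid spans whole intervals: a trailing observation short of the next
  # full grid time does not open an extra cell
  gmax <- floor(max(t) / interval_s + 1e-9)
  dt <- abs(t - g * interval_s)
  sel <- g <= gmax
  t <- t[sel]; g <- g[sel]; dt <- dt[sel]
  traj <- list(frames = traj$frames[sel], cx = traj$cx[sel],
               cy = traj$cy[sel])
  # per grid cell keep the observation closest in time, earlier frame on ties
  ord <- order(g, dt, traj$frames)
  keep <- ord[!duplicated(g[ord])]
  keep <- keep[order(g[keep])]
  data.frame(grid = g[keep], time_s = g[keep] * interval_s,
             x = traj$cx[keep], y = traj$cy[keep])
}

#' Per-step displacement series in cm
#'
#' Euclidean step distances between consecutive points of a resampled
#' trajectory, converted to cm through the pen calibration. Steps are only
#' taken within contiguous grid runs — no distance is charged across a gap.
#' Steps shorter than \code{deadband_cm} are zeroed: displacements that small
#' are body perturbation, not locomotion.
#'
#' @param points Output of \code{\link{resample_trajectory}}.
#' @param calib A \code{\link{calibrate_pen}} object.
#' @param deadband_cm Deadband in cm (0 disables the filter).
#' @return Numeric vector of step distances in cm, one per within-run
#'   consecutive pair (possibly empty).
#' @export
displacement_series <- function(points, calib, deadband_cm = 0) {
  stopifnot(deadband_cm >= 0)
  n <- nrow(points)
  if (n < 2) return(numeric(0))
  contig <- diff(points$grid) == 1L
  dx <- diff(points$x) * calib$cm_per_px_x
  dy <- diff(points$y) * calib$cm_per_px_y
  d <- sqrt(dx^2 + dy^2)[contig]
  d[d < deadband_cm] <- 0
  d
}

#' Per-bird mobility summary
#'
#' Total distance, mean speed and appearance percentage for one bird's
#' trajectory over a recording period. The speed denominator is the observed
#' contiguous duration (number of measured steps times the sampling
#' interval), not the wall-clock period, so birds hidden part of the time are
#' not biased toward zero speed.
#'
#' @param traj A trajectory object in px.
#' @param calib A \code{\link{calibrate_pen}} object.
#' @param config A \code{\link{run_config}}.
#' @param total_frames Number of frames in the period (for appearance %).
#' @param period Optional period label (e.g. an hour tag).
#' @return A one-row data frame: \code{bird_id}, \code{period},
#'   \code{total_distance} (cm), \code{mean_speed} (cm/s),
#'   \code{appearance_pct}, \code{n_observations}.
#' @export
bird_summary <- function(traj, calib, config, total_frames,
                         period = NA_character_) {
  pts <- resample_trajectory(traj, config$sample_interval, config$frame_rate)
  steps <- displacement_series(pts, calib, config$deadband)
  total <- sum(steps)
  dur <- length(steps) * config$sample_interval
  data.frame(bird_id = traj$bird_id,
             period = period,
             total_distance = total,
             mean_speed = if (dur > 0) total / dur else 0,
             appearance_pct = appearance_percentage(traj, total_frames),
             n_observations = length(traj$frames))
}

#' Flock-level mobility summary
#'
#' Mean and standard deviation over birds of total distance and mean speed.
#'
#' @param summaries A data frame of per-bird rows from
#'   \code{\link{bird_summary}} (stacked with \code{rbind}).
#' @param period Optional period label.
#' @return A one-row data frame with \code{n_birds}, distance and speed
#'   means and SDs (SD is \code{NA} for a single bird).
#' @export
flock_summary <- function(summaries, period = NA_character_) {
  if (is.null(summaries) || !nrow(summaries)) {
    stop("flock_summary needs at least one bird summary")
  }
  data.frame(period = period,
             n_birds = nrow(summaries),
             mean_distance = mean(summaries$total_distance),
             sd_distance = stats::sd(summaries$total_distance),
             mean_speed = mean(summaries$mean_speed),
             sd_speed = stats::sd(summaries$mean_speed))
}
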