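#' Run configuration for the tracking and mobility pipeline
#'
#' Bundles the geometric and temporal parameters shared by the tracker, the
#' ID re-association stage and the mobility summaries. All values are strictly
#' positive; \code{sample_interval * frame_rate} must be at least 1 so that the
#' resampling grid is no finer than the frame grid.
#'
#' @param frame_rate Frames per second of the detection stream.
#' @param sample_interval Resampling interval in seconds for displacement
#'   measurement. Displacements are taken between observations about one
#'   interval apart so that sub-second body perturbations do not register as
#'   locomotion; the default of 1 s reflects typical practice.
#' @param distance_threshold Re-association distance threshold in cm: a lost
#'   ID and a newly appeared ID closer than this are considered the same bird.
#'   Default 12 cm (about one body width).
#' @param max_gap Maximum temporal gap, in frames, between a track loss and a
#'   track birth for the pair to be considered for re-association.
#' @param deadband Per-step displacement in cm below which movement is treated
#'   as body perturbation and zeroed.
#' @param pen_width_cm,pen_height_cm Pen dimensions in cm.
#' @param image_width_px,image_height_px Camera frame dimensions in pixels.
#' @param min_track_length Minimum length, in frames, of an unmatched
#'   newly-born track; shorter ones are deleted as false detections.
#'
#' @return An object of class \code{run_config} (a named list).
#' @export
#' @examples
#' cfg <- run_config(frame_rate = 5)
#' cfg$distance_threshold
run_config <- function(frame_rate = 5,
                       sample_interval = 1.0,
                       distance_threshold = 12,
                       max_gap = 50,
                       deadband = 0.5,
                       pen_width_cm = 100,
                       pen_height_cm = 150,
                       image_width_px = 2592,
                       image_height_px = 1944,
                       min_track_length = 15) {
  cfg <- list(
    frame_rate = frame_rate,
    sample_interval = sample_interval,
    distance_threshold = distance_threshold,
    max_gap = max_gap,
    deadband = deadband,
    pen_width_cm = pen_width_cm,
    pen_height_cm = pen_height_cm,
    image_width_px = image_width_px,
    image_height_px = image_height_px,
    min_track_length = min_track_length
  )
  validate_run_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

validate_run_config <- function(cfg) {
  num <- vapply(cfg, function(v) is.numeric(v) && length(v) == 1 && is.finite(v),
                logical(1))
  if (!all(num)) {
    stop("run_config values must be finite numeric scalars: ",
         paste(names(cfg)[!num], collapse = ", "))
  }
  # deadband may be zero (filter off); everything else strictly positive
  strict <- setdiff(names(cfg), "deadband")
  bad <- strict[vapply(strict, function(k) cfg[[k]] <= 0, logical(1))]
  if (cfg$deadband < 0) bad <- c(bad, "deadband")
  if (length(bad)) {
    stop("run_config values must be positive: ", paste(bad, collapse = ", "))
  }
  if (cfg$sample_interval * cfg$frame_rate < 1) {
    stop("sample_interval * frame_rate must be >= 1 ",
         "(the sampling grid cannot be finer than the frame grid)")
  }
  invisible(cfg)
}

#' Load a run configuration from a YAML file
#'
#' Keys missing from the file are filled with the documented defaults of
#' \code{\link{run_config}} (1 s sampling interval, 100 cm x 150 cm pen,
#' 2592 x 1944 px frame). Unknown keys raise an error; non-positive values
#' raise a validation error naming the offending keys.
#'
#' @param path Path to a YAML file of \code{key: value} pairs; an empty file
#'   (or one containing only comments) yields all defaults.
#' @return A \code{run_config} object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) stop("config file must contain key: value pairs")
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, vals)
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration:\n")
  for (k in names(x)) cat(sprintf("  %-18s %g\n", k, x[[k]]))
  invisible(x)
}
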