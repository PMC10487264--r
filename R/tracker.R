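#' Tracker hyper-parameters
#'
#' @param gate_distance Assignment cost cutoff in px: a track-detection pair
#'   whose cost exceeds this is never matched. A practical default is about
#'   four nominal box widths (the pipeline derives it from the data when not
#'   given).
#' @param max_age Frames a track survives unmatched before termination.
#' @param min_hits Consecutive matches required before a tentative track is
#'   confirmed (and reported).
#' @param process_noise_scale,measurement_noise_scale Kalman noise variances
#'   in px^2 per component.
#' @param appearance_cost Optional hook: a
#'   \code{function(track_states, frame_dets)} returning a matrix (tracks x
#'   detections) of extra cost added to the motion cost. Default off; the
#'   tracker is then purely kinematic and occlusion-induced ID switches are
#'   repaired downstream by the re-association stage.
#' @return An object of class \code{tracker_params}.
#' @export
tracker_params <- function(gate_distance = 150,
                           max_age = 30,
                           min_hits = 3,
                           process_noise_scale = 1,
                           measurement_noise_scale = 1,
                           appearance_cost = NULL) {
  stopifnot(gate_distance > 0, max_age >= 1, min_hits >= 1,
            process_noise_scale >= 0, measurement_noise_scale >= 0)
  structure(list(gate_distance = gate_distance, max_age = max_age,
                 min_hits = min_hits,
                 process_noise_scale = process_noise_scale,
                 measurement_noise_scale = measurement_noise_scale,
                 appearance_cost = appearance_cost),
            class = "tracker_params")
}

#' Optimal track-detection assignment with gating
#'
#' Minimum-total-cost one-to-one matching (Hungarian algorithm, via
#' \code{clue::solve_LSAP}) between predicted track centroids and detection
#' centroids under Euclidean cost, followed by gating: any matched pair whose
#' cost exceeds \code{gate_distance} is dissolved into unmatched on both
#' sides.
#'
#' @param track_centroids Numeric matrix (n x 2) of predicted centroids.
#' @param det_centroids Numeric matrix (m x 2) of detection centroids.
#' @param gate_distance Cost cutoff.
#' @param cost Optional precomputed (n x m) cost matrix overriding the
#'   Euclidean cost (used for appearance-augmented costs).
#' @return A list: \code{matches} (2-column matrix of track and detection
#'   indices), \code{match_costs}, \code{unmatched_tracks},
#'   \code{unmatched_dets}.
#' @export
associate_detections <- function(track_centroids, det_centroids,
                                 gate_distance, cost = NULL) {
  n <- nrow(track_centroids); m <- nrow(det_centroids)
  empty <- list(matches = matrix(integer(0), 0, 2,
                                 dimnames = list(NULL, c("track", "det"))),
                match_costs = numeric(0),
                unmatched_tracks = seq_len(n %||% 0),
                unmatched_dets = seq_len(m %||% 0))
  if (is.null(n) || is.null(m) || n == 0 || m == 0) return(empty)
  if (is.null(cost)) {
    dx <- outer(track_centroids[, 1], det_centroids[, 1], "-")
    dy <- outer(track_centroids[, 2], det_centroids[, 2], "-")
    cost <- sqrt(dx^2 + dy^2)
  }
  # solve_LSAP needs nrow <= ncol; every row gets a column
  if (n <= m) {
    sol <- as.integer(clue::solve_LSAP(cost))
    ti <- seq_len(n); di <- sol
  } else {
    sol <- as.integer(clue::solve_LSAP(t(cost)))
    ti <- sol; di <- seq_len(m)
  }
  costs <- cost[cbind(ti, di)]
  ok <- costs <= gate_distance
  matches <- cbind(track = ti[ok], det = di[ok])
  list(matches = matches,
       match_costs = costs[ok],
       unmatched_tracks = setdiff(seq_len(n), matches[, 1]),
       unmatched_dets = setdiff(seq_len(m), matches[, 2]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Create an empty tracker state
#'
#' The tracker state is an environment (mutated in place by
#' \code{\link{tracker_step}} for efficiency): it holds the live tracks with
#' their Kalman states and lifecycle counters, the monotone ID counter, and a
#' log of every accepted observation.
#'
#' @param params A \code{\link{tracker_params}} object.
#' @return An object of class \code{tracker_state}.
#' @export
tracker_new <- function(params = tracker_params()) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$tracks <- list()          # live tracks, named by id
  st$next_id <- 1L
  st$last_frame <- -1L
  st$confirmed <- integer(0)   # ids ever confirmed
  st$final_states <- list()    # terminal info for finished tracks
  # observation log (preallocated, grown by doubling)
  st$log <- matrix(NA_real_, nrow = 256, ncol = 8,
                   dimnames = list(NULL, c("frame", "id", "x", "y", "w", "h",
                                           "conf", "det_row")))
  st$log_n <- 0L
  class(st) <- "tracker_state"
  st
}

log_obs <- function(st, frame, id, d, det_row) {
  if (st$log_n + 1L > nrow(st$log)) {
    st$log <- rbind(st$log, matrix(NA_real_, nrow = nrow(st$log), ncol = 8))
  }
  st$log_n <- st$log_n + 1L
  st$log[st$log_n, ] <- c(frame, id, d$x, d$y, d$w, d$h, d$conf, det_row)
  st$log_n
}

#' Advance the tracker by one frame
#'
#' Predict all live tracks, optimally assign the frame's detections
#' (\code{\link{associate_detections}}), update matched tracks, spawn
#' tentative tracks from unmatched detections (IDs are monotone increasing
#' and never reused), age unmatched tracks and terminate those unmatched for
#' more than \code{max_age} frames. Tentative tracks are deleted on their
#' first miss and confirmed after \code{min_hits} consecutive matches.
#'
#' @param st A \code{\link{tracker_new}} state (mutated in place).
#' @param frame_dets Detection data frame rows for one frame (may be empty).
#'   An optional \code{.row} column carries each detection's row index in
#'   the caller's full table, stored with the observation.
#' @param frame The frame index; defaults to \code{frame_dets$frame[1]}.
#'   Must exceed the previously presented frame.
#' @return The state, invisibly.
#' @export
tracker_step <- function(st, frame_dets, frame = NULL) {
  p <- st$params
  if (is.null(frame)) {
    if (!nrow(frame_dets)) stop("frame must be given for an empty frame")
    frame <- frame_dets$frame[1]
  }
  if (nrow(frame_dets) && any(frame_dets$frame != frame)) {
    stop("frame_dets rows must all belong to frame ", frame)
  }
  if (frame <= st$last_frame) {
    stop("frames must be presented in increasing order (got ", frame,
         " after ", st$last_frame, ")")
  }
  st$last_frame <- as.integer(frame)

  nt <- length(st$tracks)
  nd <- nrow(frame_dets)
  det_rows <- if (nd && !is.null(frame_dets$.row)) frame_dets$.row else
    rep(NA_real_, nd)

  # predict
  if (nt) {
    for (i in seq_len(nt)) {
      st$tracks[[i]]$state <- kf_predict(st$tracks[[i]]$state,
                                         p$process_noise_scale)
    }
  }

  # associate
  if (nt && nd) {
    pred <- t(vapply(st$tracks, function(tr) tr$state$mean[1:2], numeric(2)))
    detc <- cbind(frame_dets$x + frame_dets$w / 2,
                  frame_dets$y + frame_dets$h / 2)
    cost <- NULL
    if (!is.null(p$appearance_cost)) {
      dx <- outer(pred[, 1], detc[, 1], "-")
      dy <- outer(pred[, 2], detc[, 2], "-")
      cost <- sqrt(dx^2 + dy^2) + p$appearance_cost(st$tracks, frame_dets)
    }
    asg <- associate_detections(pred, detc, p$gate_distance, cost)
  } else {
    asg <- list(matches = matrix(integer(0), 0, 2),
                unmatched_tracks = seq_len(nt), unmatched_dets = seq_len(nd))
  }

  # update matched
  if (nrow(asg$matches)) {
    for (k in seq_len(nrow(asg$matches))) {
      i <- asg$matches[k, 1]; j <- asg$matches[k, 2]
      d <- frame_dets[j, ]
      tr <- st$tracks[[i]]
      tr$state <- kf_update(tr$state,
                            c(d$x + d$w / 2, d$y + d$h / 2, d$w, d$h),
                            p$measurement_noise_scale)
      tr$hit_streak <- tr$hit_streak + 1L
      tr$miss_count <- 0L
      tr$last_frame <- as.integer(frame)
      li <- log_obs(st, frame, tr$id, d, det_rows[j])
      if (tr$status == "tentative") {
        tr$tentative_log <- c(tr$tentative_log, li)
        if (tr$hit_streak >= p$min_hits) {
          tr$status <- "confirmed"
          st$confirmed <- c(st$confirmed, tr$id)
          tr$tentative_log <- integer(0)
        }
      }
      st$tracks[[i]] <- tr
    }
  }

  # age / delete / terminate unmatched tracks
  drop_idx <- integer(0)
  for (i in asg$unmatched_tracks) {
    tr <- st$tracks[[i]]
    if (tr$status == "tentative") {
      # a tentative track missing once is discarded along with its log rows
      st$log[tr$tentative_log, "id"] <- NA_real_
      drop_idx <- c(drop_idx, i)
    } else {
      tr$miss_count <- tr$miss_count + 1L
      tr$hit_streak <- 0L
      if (tr$miss_count > p$max_age) {
        tr$status <- "lost"
        st$final_states[[as.character(tr$id)]] <- tr
        drop_idx <- c(drop_idx, i)
      }
      st$tracks[[i]] <- tr
    }
  }
  if (length(drop_idx)) st$tracks <- st$tracks[-drop_idx]

  # spawn tentative tracks from unmatched detections
  for (j in asg$unmatched_dets) {
    d <- frame_dets[j, ]
    id <- st$next_id
    st$next_id <- st$next_id + 1L
    li <- log_obs(st, frame, id, d, det_rows[j])
    tr <- list(id = id,
               state = kf_init(c(d$x + d$w / 2, d$y + d$h / 2, d$w, d$h),
                               p$measurement_noise_scale),
               status = if (p$min_hits <= 1) "confirmed" else "tentative",
               hit_streak = 1L, miss_count = 0L,
               first_frame = as.integer(frame),
               last_frame = as.integer(frame),
               tentative_log = if (p$min_hits <= 1) integer(0) else li)
    if (tr$status == "confirmed") st$confirmed <- c(st$confirmed, id)
    st$tracks[[length(st$tracks) + 1L]] <- tr
  }
  invisible(st)
}

#' Extract confirmed tracklets from a tracker state
#'
#' @param st A \code{\link{tracker_state}}.
#' @return A list of \code{tracklet} objects (one per ID ever confirmed,
#'   sorted by ID), each with fields \code{track_id}, \code{frames},
#'   \code{cx}, \code{cy}, \code{w}, \code{h}, \code{conf}, \code{det_rows},
#'   \code{status}, \code{first_frame}, \code{last_frame} and the final
#'   Kalman \code{state}.
#' @export
tracker_tracklets <- function(st) {
  if (!length(st$confirmed)) return(list())
  log <- st$log[seq_len(st$log_n), , drop = FALSE]
  log <- log[!is.na(log[, "id"]) & log[, "id"] %in% st$confirmed, ,
             drop = FALSE]
  ids <- sort(unique(as.integer(log[, "id"])))
  live <- stats::setNames(st$tracks,
                          vapply(st$tracks, function(tr) as.character(tr$id),
                                 character(1)))
  lapply(ids, function(id) {
    rows <- log[log[, "id"] == id, , drop = FALSE]
    rows <- rows[order(rows[, "frame"]), , drop = FALSE]
    key <- as.character(id)
    info <- st$final_states[[key]] %||% live[[key]]
    structure(list(track_id = id,
                   frames = as.integer(rows[, "frame"]),
                   cx = rows[, "x"] + rows[, "w"] / 2,
                   cy = rows[, "y"] + rows[, "h"] / 2,
                   w = rows[, "w"], h = rows[, "h"],
                   conf = rows[, "conf"],
                   det_rows = rows[, "det_row"],
                   status = if (is.null(info)) "confirmed" else info$status,
                   first_frame = as.integer(rows[1, "frame"]),
                   last_frame = as.integer(rows[nrow(rows), "frame"]),
                   state = info$state),
              class = "tracklet")
  })
}

#' @export
print.tracklet <- function(x, ...) {
  cat(sprintf("Tracklet %d: %d obs, frames %d-%d (%s)\n", x$track_id,
              length(x$frames), x$first_frame, x$last_frame, x$status))
  invisible(x)
}

#' Run the tracker over a full detection stream
#'
#' Feeds every frame from 0 to \code{n_frames - 1} (frames absent from the
#' table count as empty, so tracks age through detection gaps) through
#' \code{\link{tracker_step}} and returns all tracklets ever confirmed,
#' including those terminated mid-video. Wherever a detection gap outlived
#' \code{max_age}, the bird resurfaces under a fresh ID — the identity
#' switches that \code{\link{match_lost_new}} repairs.
#'
#' @param dets A detection data frame (see \link{detection-tables}).
#' @param params A \code{\link{tracker_params}}.
#' @param n_frames Number of frames in the video; defaults to
#'   \code{max(dets$frame) + 1}.
#' @return A list of \code{tracklet} objects sorted by track ID.
#' @export
run_tracker <- function(dets, params = tracker_params(), n_frames = NULL) {
  if (is.null(n_frames)) {
    n_frames <- if (nrow(dets)) max(dets$frame) + 1L else 0L
  }
  if (!nrow(dets)) return(list())
  if (is.unsorted(dets$frame)) dets <- dets[order(dets$frame), , drop = FALSE]
  dets$.row <- seq_len(nrow(dets))
  st <- tracker_new(params)
  # index ranges per frame (frames are sorted)
  starts <- c(1L, which(diff(dets$frame) > 0) + 1L)
  ends <- c(starts[-1] - 1L, nrow(dets))
  frame_of <- dets$frame[starts]
  k <- 1L
  for (f in 0:(n_frames - 1L)) {
    if (k <= length(starts) && frame_of[k] == f) {
      tracker_step(st, dets[starts[k]:ends[k], , drop = FALSE], frame = f)
      k <- k + 1L
    } else {
      tracker_step(st, dets[0, , drop = FALSE], frame = f)
    }
  }
  tracker_tracklets(st)
}
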