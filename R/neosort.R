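#' Trajectory constructor
#'
#' A trajectory is one bird's merged centroid time series: the root ID of a
#' merge chain, its time-sorted observations, and the tracklet IDs that were
#' stitched together to form it.
#'
#' @param bird_id Integer ID (root of the merge chain).
#' @param frames Integer frame indices, strictly increasing.
#' @param cx,cy Centroid coordinates (px unless converted).
#' @param w,h Box dimensions per observation.
#' @param source_ids Integer vector of merged tracklet IDs.
#' @return An object of class \code{trajectory}.
#' @export
new_trajectory <- function(bird_id, frames, cx, cy, w = NULL, h = NULL,
                           source_ids = bird_id) {
  if (length(frames) > 1 && any(diff(frames) <= 0)) {
    stop("trajectory frames must be strictly increasing")
  }
  n <- length(frames)
  rec <- function(v) {
    if (is.null(v) || !n) return(v)
    if (length(v) == 1) return(rep(v, n))
    if (length(v) != n) stop("coordinate length must be 1 or match frames")
    v
  }
  structure(list(bird_id = as.integer(bird_id), frames = as.integer(frames),
                 cx = rec(cx), cy = rec(cy), w = rec(w), h = rec(h),
                 source_ids = as.integer(source_ids)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory %d: %d obs, frames %d-%d, merged from {%s}\n",
              x$bird_id, length(x$frames),
              if (length(x$frames)) min(x$frames) else NA,
              if (length(x$frames)) max(x$frames) else NA,
              paste(x$source_ids, collapse = ", ")))
  invisible(x)
}

#' Detect track-loss and track-birth events
#'
#' Scans the tracker's output for the raw material of ID re-association:
#' every tracklet that ends before the end of the video emits a loss event
#' at its final observation's position, and every tracklet born after the
#' initial spawn cohort (tracks starting within the first
#' \code{spawn_window} frames) emits a birth event at its first
#' observation's position.
#'
#' @param tracklets List of tracklets from \code{\link{run_tracker}}.
#' @param video_end Index of the last frame of the video.
#' @param spawn_window Frames 0 .. spawn_window - 1 count as the initial
#'   cohort whose births are not events (default 3, the tracker's usual
#'   confirmation length).
#' @return A list with data frames \code{losses} (\code{track_id},
#'   \code{last_frame}, \code{x}, \code{y}) and \code{births}
#'   (\code{track_id}, \code{first_frame}, \code{x}, \code{y},
#'   \code{length}).
#' @export
find_events <- function(tracklets, video_end, spawn_window = 3) {
  losses <- births <- NULL
  for (tk in tracklets) {
    n <- length(tk$frames)
    if (!n) next
    if (tk$last_frame < video_end) {
      losses <- rbind(losses, data.frame(track_id = tk$track_id,
                                         last_frame = tk$last_frame,
                                         x = tk$cx[n], y = tk$cy[n]))
    }
    if (tk$first_frame >= spawn_window) {
      births <- rbind(births, data.frame(track_id = tk$track_id,
                                         first_frame = tk$first_frame,
                                         x = tk$cx[1], y = tk$cy[1],
                                         length = n))
    }
  }
  empty_l <- data.frame(track_id = integer(0), last_frame = integer(0),
                        x = numeric(0), y = numeric(0))
  empty_b <- data.frame(track_id = integer(0), first_frame = integer(0),
                        x = numeric(0), y = numeric(0), length = integer(0))
  list(losses = losses %||% empty_l, births = births %||% empty_b)
}

#' Associate lost IDs with newly appeared IDs
#'
#' The ID-repair rule: a lost track and a subsequently born track are
#' candidates for being the same bird when the birth follows the loss by at
#' most \code{max_gap} frames and the two event positions lie closer than
#' \code{distance_threshold}. Over all candidate pairs a globally
#' minimum-total-distance one-to-one matching is taken (Hungarian
#' assignment; leaving a pair unmatched is allowed and distance ties break
#' toward the earlier birth). Matched pairs become merges; unmatched births
#' whose tracklet is shorter than \code{min_track_length} frames are deleted
#' as false detections; everything else is left unresolved. Merges compose
#' transitively into chains (A lost -> B, B lost -> C).
#'
#' @param losses,births Event data frames from \code{\link{find_events}}.
#' @param distance_threshold Threshold distance, in the same units as the
#'   event positions.
#' @param max_gap Maximum frames between loss and birth.
#' @param min_track_length Deletion rule: unmatched new tracks shorter than
#'   this many observations are false detections.
#' @return An object of class \code{id_mapping}: \code{merges} (data frame
#'   \code{lost_id}, \code{new_id}, \code{distance}, \code{gap}),
#'   \code{deletions}, \code{unresolved} (integer vectors).
#' @export
match_lost_new <- function(losses, births, distance_threshold, max_gap,
                           min_track_length = 1) {
  stopifnot(distance_threshold > 0, max_gap >= 1)
  nl <- nrow(losses); nb <- nrow(births)
  merges <- data.frame(lost_id = integer(0), new_id = integer(0),
                       distance = numeric(0), gap = integer(0))
  if (nl && nb) {
    gap <- outer(births$first_frame, losses$last_frame, "-") # nb x nl
    d <- sqrt(outer(births$x, losses$x, "-")^2 +
                outer(births$y, losses$y, "-")^2)
    feasible <- gap > 0 & gap <= max_gap & d < distance_threshold
    if (any(feasible)) {
      BIG <- 1e15
      # dummy columns at cost K (K exceeds any achievable distance total) let
      # births stay unmatched but make every feasible merge cheaper than not
      # merging, so the assignment maximizes the number of merges first, then
      # minimizes total distance; eps breaks distance ties toward the earlier
      # birth; solve_LSAP needs non-negative costs
      K <- (nb + 1) * distance_threshold
      eps <- distance_threshold * 1e-9
      cost <- ifelse(feasible, d + eps * births$first_frame, BIG)
      cost <- cbind(cost, matrix(K, nb, nb))
      sol <- as.integer(clue::solve_LSAP(cost))
      for (b in seq_len(nb)) {
        l <- sol[b]
        if (l <= nl && feasible[b, l]) {
          merges <- rbind(merges,
                          data.frame(lost_id = losses$track_id[l],
                                     new_id = births$track_id[b],
                                     distance = d[b, l],
                                     gap = gap[b, l]))
        }
      }
    }
  }
  matched_births <- merges$new_id
  unmatched <- births[!(births$track_id %in% matched_births), , drop = FALSE]
  deletions <- unmatched$track_id[unmatched$length < min_track_length]
  event_ids <- union(losses$track_id, births$track_id)
  unresolved <- setdiff(event_ids, c(merges$lost_id, merges$new_id, deletions))
  structure(list(merges = merges,
                 deletions = as.integer(deletions),
                 unresolved = as.integer(sort(unresolved))),
            class = "id_mapping")
}

#' @export
print.id_mapping <- function(x, ...) {
  cat(sprintf("ID mapping: %d merge(s), %d deletion(s), %d unresolved\n",
              nrow(x$merges), length(x$deletions), length(x$unresolved)))
  if (nrow(x$merges)) {
    for (i in seq_len(nrow(x$merges))) {
      cat(sprintf("  %d <- %d (%.1f apart, %d-frame gap)\n",
                  x$merges$lost_id[i], x$merges$new_id[i],
                  x$merges$distance[i], x$merges$gap[i]))
    }
  }
  invisible(x)
}

# resolve each id to the root (head) of its merge chain
resolve_roots <- function(ids, merges) {
  parent <- stats::setNames(merges$lost_id, as.character(merges$new_id))
  vapply(ids, function(id) {
    seen <- integer(0)
    while (as.character(id) %in% names(parent)) {
      if (id %in% seen) stop("merge chains must be acyclic")
      seen <- c(seen, id)
      id <- parent[[as.character(id)]]
    }
    as.integer(id)
  }, integer(1))
}

#' Merge tracklets into bird-level trajectories
#'
#' Applies an ID mapping: tracklets in a merge chain are concatenated
#' time-sorted into one trajectory under the chain's root (earliest) ID,
#' deleted tracklets are dropped, and every remaining tracklet becomes a
#' singleton trajectory. Observations are conserved: none is duplicated,
#' and none disappears except through the deletion rule. Chain members
#' overlapping in frame range indicate a corrupt mapping and raise an error.
#'
#' @param tracklets List of tracklets from \code{\link{run_tracker}}.
#' @param mapping An \code{\link{match_lost_new}} result.
#' @return A list of \code{\link{new_trajectory}} objects sorted by bird ID.
#' @export
merge_tracklets <- function(tracklets, mapping) {
  ids <- vapply(tracklets, `[[`, integer(1), "track_id")
  keep <- !(ids %in% mapping$deletions)
  tracklets <- tracklets[keep]
  ids <- ids[keep]
  if (!length(tracklets)) return(list())
  roots <- resolve_roots(ids, mapping$merges)
  out <- lapply(split(seq_along(tracklets), roots), function(idx) {
    tks <- tracklets[idx]
    starts <- vapply(tks, `[[`, integer(1), "first_frame")
    tks <- tks[order(starts)]
    frames <- unlist(lapply(tks, `[[`, "frames"))
    if (length(tks) > 1) {
      ends <- vapply(tks, `[[`, integer(1), "last_frame")
      starts <- vapply(tks, `[[`, integer(1), "first_frame")
      if (any(starts[-1] <= ends[-length(ends)])) {
        stop("merge chain members overlap in frame range (ids ",
             paste(vapply(tks, `[[`, integer(1), "track_id"),
                   collapse = ", "), ")")
      }
    }
    tr <- new_trajectory(
      bird_id = min(vapply(tks, `[[`, integer(1), "track_id")),
      frames = frames,
      cx = unlist(lapply(tks, `[[`, "cx")),
      cy = unlist(lapply(tks, `[[`, "cy")),
      w = unlist(lapply(tks, `[[`, "w")),
      h = unlist(lapply(tks, `[[`, "h")),
      source_ids = vapply(tks, `[[`, integer(1), "track_id"))
    tr$det_rows <- unlist(lapply(tks, `[[`, "det_rows"))
    tr
  })
  out <- unname(out)
  out[order(vapply(out, `[[`, integer(1), "bird_id"))]
}

#' Appearance percentage of a trajectory
#'
#' Share of the recording in which the bird has an observation:
#' \code{100 * observed frames / total_frames}. Even a bird visible only
#' half the time yields a usable mobility estimate, but the appearance
#' percentage must be reported alongside so partial coverage is explicit.
#'
#' @param traj A trajectory object.
#' @param total_frames Total frames in the recording period (>= 1).
#' @return A percentage in [0, 100].
#' @export
appearance_percentage <- function(traj, total_frames) {
  stopifnot(total_frames >= 1)
  100 * length(unique(traj$frames)) / total_frames
}

#' Sweep the re-association distance threshold
#'
#' The threshold has no canonical value — it is chosen by trial and error
#' per setup — so this utility reports, for each candidate threshold, how
#' many merges and deletions the mapping would contain. Merge counts are
#' non-decreasing in the threshold.
#'
#' @param tracklets List of tracklets.
#' @param video_end Last frame index.
#' @param thresholds Numeric vector of candidate distance thresholds.
#' @param max_gap,min_track_length,spawn_window Passed through to
#'   \code{\link{find_events}} / \code{\link{match_lost_new}}.
#' @param plot Draw a base-graphics line plot of merges vs threshold.
#' @return A data frame: \code{threshold}, \code{n_merges},
#'   \code{n_deletions}.
#' @export
sweep_threshold <- function(tracklets, video_end, thresholds,
                            max_gap = 50, min_track_length = 1,
                            spawn_window = 3, plot = FALSE) {
  ev <- find_events(tracklets, video_end, spawn_window)
  res <- do.call(rbind, lapply(thresholds, function(th) {
    m <- match_lost_new(ev$losses, ev$births, th, max_gap, min_track_length)
    data.frame(threshold = th, n_merges = nrow(m$merges),
               n_deletions = length(m$deletions))
  }))
  if (plot) {
    graphics::plot(res$threshold, res$n_merges, type = "b", pch = 16,
                   xlab = "distance threshold", ylab = "merges",
                   main = "Re-association merges vs threshold")
  }
  res
}
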