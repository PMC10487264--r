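#' Simulation configuration
#'
#' Conditions of the simulated pen. Defaults mirror a typical top-down
#' broiler-pen recording setup: a 100 cm x 150 cm pen holding 12 birds
#' (use 16 for the higher stocking density), recorded for 15 min (900 s).
#' Broilers alternate rest and short travel bouts; the motion law is a
#' pause-and-travel waypoint walk with per-frame pause probability 0.7 and
#' travel speed around 3 cm/s, values chosen as realistic for mid-grow-out
#' birds since no canonical motion model exists.
#'
#' @param n_birds Number of birds in the pen.
#' @param pen_width_cm,pen_height_cm Pen dimensions in cm.
#' @param duration_s Recording duration in seconds.
#' @param frame_rate Frames per second.
#' @param mean_speed_cm_s Mean travel speed in cm/s; per travel bout the
#'   speed is drawn from Normal(mean, 0.2 * mean), truncated at 0.
#' @param pause_prob Per-frame probability that a bird rests in place.
#' @param perturb_sd_cm SD (cm) of the small positional perturbation while
#'   resting — body movement below the deadband scale, not locomotion.
#' @param bird_radius_cm Half body width in cm; sets the rendered box size
#'   and the occlusion contact distance. Increase it between runs to model
#'   bird growth.
#' @param seed Integer RNG seed; the simulation is bit-reproducible given
#'   the seed.
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(n_birds = 12,
                       pen_width_cm = 100,
                       pen_height_cm = 150,
                       duration_s = 900,
                       frame_rate = 5,
                       mean_speed_cm_s = 3,
                       pause_prob = 0.7,
                       perturb_sd_cm = 0.05,
                       bird_radius_cm = 6,
                       seed = 1L) {
  stopifnot(n_birds >= 1, pen_width_cm > 0, pen_height_cm > 0,
            duration_s > 0, frame_rate > 0, mean_speed_cm_s >= 0,
            pause_prob >= 0, pause_prob <= 1, perturb_sd_cm >= 0,
            bird_radius_cm > 0, bird_radius_cm * 2 <= pen_width_cm)
  structure(list(n_birds = as.integer(n_birds),
                 pen_width_cm = pen_width_cm, pen_height_cm = pen_height_cm,
                 duration_s = duration_s, frame_rate = frame_rate,
                 mean_speed_cm_s = mean_speed_cm_s, pause_prob = pause_prob,
                 perturb_sd_cm = perturb_sd_cm,
                 bird_radius_cm = bird_radius_cm,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Detection-noise configuration
#'
#' Corruption model for turning ground-truth positions into a realistic
#' detection stream. Defaults are calibrated qualitatively so that a
#' 12-bird pen averages around 9-10 detected birds per frame, the regime a
#' single-class detector shows on crowded pens.
#'
#' @param occlusion_dropout_prob Probability that a bird in contact with
#'   another (center distance below two body radii) starts a dropout.
#' @param base_miss_prob Per-frame per-bird probability of starting a
#'   dropout with no occlusion.
#' @param false_pos_rate Expected spurious detections per frame (Poisson).
#' @param jitter_sd_cm SD (cm) of Gaussian noise on detected centroids.
#' @param gap_extension_prob Probability that an ongoing dropout persists
#'   into the next frame, producing multi-frame gaps (mean gap length
#'   \code{1 / (1 - gap_extension_prob)} frames).
#' @return An object of class \code{noise_config}.
#' @export
noise_config <- function(occlusion_dropout_prob = 0.5,
                         base_miss_prob = 0.05,
                         false_pos_rate = 0.1,
                         jitter_sd_cm = 0.2,
                         gap_extension_prob = 0.8) {
  probs <- c(occlusion_dropout_prob, base_miss_prob, gap_extension_prob)
  stopifnot(all(probs >= 0), all(probs <= 1), false_pos_rate >= 0,
            jitter_sd_cm >= 0)
  structure(list(occlusion_dropout_prob = occlusion_dropout_prob,
                 base_miss_prob = base_miss_prob,
                 false_pos_rate = false_pos_rate,
                 jitter_sd_cm = jitter_sd_cm,
                 gap_extension_prob = gap_extension_prob),
            class = "noise_config")
}

#' The zero-noise configuration (every bird detected exactly, no clutter)
#' @return A \code{\link{noise_config}} with all corruption off.
#' @export
no_noise <- function() {
  noise_config(occlusion_dropout_prob = 0, base_miss_prob = 0,
               false_pos_rate = 0, jitter_sd_cm = 0, gap_extension_prob = 0)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulate ground-truth bird motion in a pen
#'
#' Pause-and-travel waypoint walk: each frame a bird either rests with
#' probability \code{pause_prob} (staying put up to a perturbation of SD
#' \code{perturb_sd_cm}) or advances toward its current waypoint, drawn
#' uniformly in the pen, at its bout speed (drawn per bout from
#' Normal(mean, 0.2 mean), truncated at 0). Reaching the waypoint draws a
#' fresh waypoint and bout speed. Positions are confined to the pen with a
#' margin of one body radius, and birds are solid: a move that would bring
#' two centers closer than one body radius is blocked (the blocked bird
#' stands and re-routes), so birds can press against and partly overlap
#' each other — triggering occlusions — but never coincide. The walk is
#' deterministic given \code{config$seed}. The expected total path length
#' is approximately
#' \code{(1 - pause_prob) * mean_speed_cm_s * duration_s}.
#'
#' @param config A \code{\link{sim_config}}.
#' @return A data frame of ground-truth tracks: \code{bird_id},
#'   \code{frame}, \code{x_cm}, \code{y_cm}, dense in frame for every bird.
#' @export
simulate_motion <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_birds
    n_frames <- as.integer(round(config$duration_s * config$frame_rate))
    r <- config$bird_radius_cm
    min_sep2 <- r^2   # centers may close to one radius, never further
    lo <- c(r, r)
    hi <- c(config$pen_width_cm - r, config$pen_height_cm - r)
    draw_speed <- function(k) {
      if (config$mean_speed_cm_s == 0) return(rep(0, k))
      pmax(stats::rnorm(k, config$mean_speed_cm_s,
                        0.2 * config$mean_speed_cm_s), 0)
    }
    draw_point <- function() c(stats::runif(1, lo[1], hi[1]),
                               stats::runif(1, lo[2], hi[2]))
    clear_of_others <- function(p, pos, i) {
      if (n == 1) return(TRUE)
      d2 <- (pos[-i, 1] - p[1])^2 + (pos[-i, 2] - p[2])^2
      all(d2 >= min_sep2)
    }
    # initial positions: sequential rejection sampling at the separation
    pos <- matrix(NA_real_, n, 2)
    for (i in seq_len(n)) {
      repeat {
        p <- draw_point()
        prev <- seq_len(i - 1)
        if (!length(prev) ||
            all((pos[prev, 1] - p[1])^2 + (pos[prev, 2] - p[2])^2 >=
                  min_sep2)) {
          pos[i, ] <- p
          break
        }
      }
    }
    wp <- t(vapply(seq_len(n), function(i) draw_point(), numeric(2)))
    spd <- draw_speed(n)
    X <- matrix(NA_real_, n_frames, n)
    Y <- matrix(NA_real_, n_frames, n)
    X[1, ] <- pos[, 1]; Y[1, ] <- pos[, 2]
    if (n_frames > 1) for (f in 2:n_frames) {
      paused <- stats::runif(n) < config$pause_prob
      for (i in seq_len(n)) {
        if (paused[i]) {
          if (config$perturb_sd_cm > 0 && config$mean_speed_cm_s > 0) {
            cand <- pos[i, ] + stats::rnorm(2, 0, config$perturb_sd_cm)
            cand <- pmin(pmax(cand, lo), hi)
            if (clear_of_others(cand, pos, i)) pos[i, ] <- cand
          }
          next
        }
        cand <- pos[i, ]
        remaining <- spd[i] / config$frame_rate
        while (remaining > 0) {
          to_wp <- wp[i, ] - cand
          dist_wp <- sqrt(sum(to_wp^2))
          if (dist_wp <= remaining) {
            cand <- wp[i, ]
            remaining <- remaining - dist_wp
            wp[i, ] <- draw_point()
            spd[i] <- draw_speed(1)
            if (dist_wp == 0) break
          } else {
            cand <- cand + to_wp / dist_wp * remaining
            remaining <- 0
          }
        }
        if (clear_of_others(cand, pos, i)) {
          pos[i, ] <- cand
        } else {
          # blocked by another bird: stand this frame, head elsewhere
          wp[i, ] <- draw_point()
          spd[i] <- draw_speed(1)
        }
      }
      X[f, ] <- pos[, 1]; Y[f, ] <- pos[, 2]
    }
    data.frame(bird_id = rep(seq_len(n), each = n_frames),
               frame = rep(0:(n_frames - 1L), times = n),
               x_cm = as.vector(X), y_cm = as.vector(Y))
  })
}

#' Ground-truth path length per bird
#'
#' Total Euclidean path length of each bird's ground-truth track, optionally
#' at a coarser sampling (every \code{every}-th frame), for scoring pipeline
#' output against truth.
#'
#' @param tracks Ground-truth data frame from \code{\link{simulate_motion}}.
#' @param every Keep every \code{every}-th frame before summing steps
#'   (1 = full rate; \code{frame_rate * sample_interval} matches the
#'   mobility stage's grid).
#' @return Named numeric vector of path lengths in cm, one per bird.
#' @export
truth_path_length <- function(tracks, every = 1) {
  every <- as.integer(every)
  stopifnot(every >= 1)
  vapply(split(tracks, tracks$bird_id), function(g) {
    g <- g[order(g$frame), ]
    keep <- g$frame %% every == 0L
    sum(sqrt(diff(g$x_cm[keep])^2 + diff(g$y_cm[keep])^2))
  }, numeric(1))
}

#' Corrupt ground-truth tracks into a detection stream
#'
#' Emulates a real detector on a crowded pen. Per frame, each bird is
#' detected unless a dropout is active for it. A new dropout starts when a
#' base miss fires, or when the bird is in contact with another (center
#' distance under two body radii) and an occlusion dropout fires; an active
#' dropout persists into the next frame with \code{gap_extension_prob},
#' producing the multi-frame gaps that break tracks. Detected boxes are
#' centered on the true centroid plus Gaussian jitter, with a fixed nominal
#' box size of two body radii; false positives are placed uniformly in the
#' pen (Poisson count per frame). True detections draw confidences from
#' U(0.55, 1), false positives from U(0.5, 0.9).
#'
#' @param tracks Ground-truth data frame from \code{\link{simulate_motion}}.
#' @param noise A \code{\link{noise_config}}.
#' @param calib A \code{\link{calibrate_pen}} mapping cm to px.
#' @param seed Integer seed for the corruption draws.
#' @param bird_radius_cm Body radius in cm (match the motion config).
#' @param pen_width_cm,pen_height_cm Pen dimensions in cm (match the motion
#'   config); used to place false positives and clamp boxes to the image.
#' @return A detection data frame with a \code{truth_id} column labelling
#'   each detection with its generating bird (-1 for false positives).
#' @export
render_detections <- function(tracks, noise, calib, seed = 1L,
                              bird_radius_cm = 6,
                              pen_width_cm = 100, pen_height_cm = 150) {
  stopifnot(inherits(noise, "noise_config"),
            inherits(calib, "pen_calibration"))
  with_seed(seed, {
    ids <- sort(unique(tracks$bird_id))
    n <- length(ids)
    frames <- sort(unique(tracks$frame))
    # dense bird x frame position matrices
    ord <- order(tracks$bird_id, tracks$frame)
    tr <- tracks[ord, ]
    nf <- length(frames)
    if (nrow(tr) != n * nf) stop("ground-truth tracks must be dense in frame")
    Xcm <- matrix(tr$x_cm, nrow = nf, ncol = n)
    Ycm <- matrix(tr$y_cm, nrow = nf, ncol = n)
    w_px <- 2 * bird_radius_cm / calib$cm_per_px_x
    h_px <- 2 * bird_radius_cm / calib$cm_per_px_y
    pen_w_px <- pen_width_cm / calib$cm_per_px_x
    pen_h_px <- pen_height_cm / calib$cm_per_px_y
    contact2 <- (2 * bird_radius_cm)^2

    in_dropout <- rep(FALSE, n)
    out <- vector("list", nf)
    for (fi in seq_len(nf)) {
      px <- Xcm[fi, ]; py <- Ycm[fi, ]
      # dropout persistence, then new dropout triggers
      persisting <- in_dropout & (stats::runif(n) < noise$gap_extension_prob)
      overlapped <- rep(FALSE, n)
      if (n > 1 && noise$occlusion_dropout_prob > 0) {
        d2 <- outer(px, px, "-")^2 + outer(py, py, "-")^2
        diag(d2) <- Inf
        overlapped <- apply(d2 < contact2, 1, any)
      }
      fresh <- !persisting &
        ((stats::runif(n) < noise$base_miss_prob) |
           (overlapped & stats::runif(n) < noise$occlusion_dropout_prob))
      in_dropout <- persisting | fresh
      det <- which(!in_dropout)
      nfp <- if (noise$false_pos_rate > 0)
        stats::rpois(1, noise$false_pos_rate) else 0L
      if (!length(det) && !nfp) next
      cx <- px[det] / calib$cm_per_px_x
      cy <- py[det] / calib$cm_per_px_y
      if (noise$jitter_sd_cm > 0 && length(det)) {
        cx <- cx + stats::rnorm(length(det), 0,
                                noise$jitter_sd_cm / calib$cm_per_px_x)
        cy <- cy + stats::rnorm(length(det), 0,
                                noise$jitter_sd_cm / calib$cm_per_px_y)
      }
      conf <- stats::runif(length(det), 0.55, 1)
      tid <- ids[det]
      if (nfp > 0) {
        cx <- c(cx, stats::runif(nfp, w_px / 2, pen_w_px - w_px / 2))
        cy <- c(cy, stats::runif(nfp, h_px / 2, pen_h_px - h_px / 2))
        conf <- c(conf, stats::runif(nfp, 0.5, 0.9))
        tid <- c(tid, rep(-1L, nfp))
      }
      x <- pmin(pmax(cx - w_px / 2, 0), pen_w_px - w_px)
      y <- pmin(pmax(cy - h_px / 2, 0), pen_h_px - h_px)
      out[[fi]] <- data.frame(frame = frames[fi], x = x, y = y,
                              w = w_px, h = h_px, conf = conf,
                              truth_id = as.integer(tid))
    }
    out <- out[!vapply(out, is.null, logical(1))]
    if (!length(out)) return(empty_detections(truth = TRUE))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Inject controlled occlusion dropouts into a detection stream
#'
#' Removes a bird's detections over randomly placed frame windows, emulating
#' isolated occlusion events (one bird gliding over another) under
#' controlled conditions: each event's window length is drawn from
#' \code{len_range}, events are separated in time by at least
#' \code{buffer_frames}, and a window is only accepted if the bird's net
#' ground-truth displacement across it is below \code{max_disp_cm} and its
#' walked path during it below \code{max_path_cm}. Constraining the walked
#' path selects rest bouts — the regime real occlusions occupy, since they
#' arise from resting, huddled birds gliding over one another, and the only
#' regime in which distance can be recovered: a bird's path while hidden is
#' unobservable in principle. Deterministic given \code{seed}.
#'
#' @param dets A detection data frame with a \code{truth_id} column.
#' @param truth Ground-truth tracks (\code{\link{simulate_motion}} output).
#' @param n_events Number of dropout events to inject.
#' @param len_range Integer two-vector: minimum and maximum window length
#'   in frames.
#' @param max_disp_cm Maximum net displacement of the bird between the
#'   frames bounding the window.
#' @param max_path_cm Maximum ground-truth path length walked by the bird
#'   inside the window (default unbounded; set a small value to restrict
#'   events to rest bouts).
#' @param buffer_frames Minimum separation between event windows (and from
#'   the recording's ends).
#' @param seed RNG seed.
#' @return A list: \code{dets} (the thinned table) and \code{events}
#'   (data frame \code{bird_id}, \code{start}, \code{end}). Fewer than
#'   \code{n_events} rows are returned if placement runs out of room.
#' @export
inject_dropouts <- function(dets, truth, n_events, len_range = c(6, 25),
                            max_disp_cm = 6, max_path_cm = Inf,
                            buffer_frames = 20, seed = 1L) {
  stopifnot(length(len_range) == 2, len_range[1] >= 1,
            len_range[2] >= len_range[1], n_events >= 1)
  with_seed(seed, {
    n_frames <- max(truth$frame) + 1L
    birds <- sort(unique(truth$bird_id))
    events <- data.frame(bird_id = integer(0), start = integer(0),
                         end = integer(0))
    tries <- 0L
    while (nrow(events) < n_events && tries < 200L * n_events) {
      tries <- tries + 1L
      b <- sample(birds, 1)
      len <- sample(len_range[1]:len_range[2], 1)
      start <- sample(seq(buffer_frames,
                          n_frames - 1L - buffer_frames - len), 1)
      end <- start + len - 1L
      if (nrow(events) &&
          any(start <= events$end + buffer_frames &
                end >= events$start - buffer_frames)) next
      g <- truth[truth$bird_id == b & truth$frame >= start - 1L &
                   truth$frame <= end + 1L, ]
      g <- g[order(g$frame), ]
      disp <- sqrt((g$x_cm[nrow(g)] - g$x_cm[1])^2 +
                     (g$y_cm[nrow(g)] - g$y_cm[1])^2)
      if (disp >= max_disp_cm) next
      if (is.finite(max_path_cm)) {
        path <- sum(sqrt(diff(g$x_cm)^2 + diff(g$y_cm)^2))
        if (path >= max_path_cm) next
      }
      events <- rbind(events,
                      data.frame(bird_id = b, start = start, end = end))
    }
    keep <- rep(TRUE, nrow(dets))
    for (k in seq_len(nrow(events))) {
      keep <- keep & !(dets$truth_id == events$bird_id[k] &
                         dets$frame >= events$start[k] &
                         dets$frame <= events$end[k])
    }
    list(dets = dets[keep, , drop = FALSE],
         events = events[order(events$start), , drop = FALSE])
  })
}

#' Accept/reject split for pseudo-labeling
#'
#' Semi-supervised bookkeeping: a frame is accepted as pseudo-labeled only
#' if every detection in it has confidence at or above the threshold;
#' frames containing any low-confidence detection are rejected.
#'
#' @param dets A detection data frame.
#' @param confidence_threshold Threshold in [0, 1].
#' @return A list: \code{accepted} and \code{rejected} detection data
#'   frames, plus frame counts \code{n_accepted} and \code{n_rejected}.
#' @export
ssl_split <- function(dets, confidence_threshold) {
  if (!is.numeric(confidence_threshold) || length(confidence_threshold) != 1 ||
      confidence_threshold < 0 || confidence_threshold > 1) {
    stop("confidence_threshold must be a single value in [0, 1]")
  }
  if (!nrow(dets)) {
    return(list(accepted = dets, rejected = dets,
                n_accepted = 0L, n_rejected = 0L))
  }
  min_conf <- tapply(dets$conf, dets$frame, min)
  ok_frames <- as.integer(names(min_conf))[min_conf >= confidence_threshold]
  acc <- dets$frame %in% ok_frames
  list(accepted = dets[acc, , drop = FALSE],
       rejected = dets[!acc, , drop = FALSE],
       n_accepted = length(ok_frames),
       n_rejected = length(unique(dets$frame)) - length(ok_frames))
}
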