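make_tracklet <- function(id, frames, cx, cy, w = 10, h = 10) {
  n <- length(frames)
  structure(list(track_id = as.integer(id), frames = as.integer(frames),
                 cx = rep_len(cx, n), cy = rep_len(cy, n),
                 w = rep_len(w, n), h = rep_len(h, n),
                 conf = rep(1, n), det_rows = rep(NA_real_, n),
                 status = "confirmed",
                 first_frame = as.integer(frames[1]),
                 last_frame = as.integer(frames[n])),
            class = "tracklet")
}

test_that("full-span tracklets emit no events; fragments emit loss and birth", {
  full <- lapply(1:12, function(i) make_tracklet(i, 0:99, cx = i * 10, cy = 5))
  ev <- find_events(full, video_end = 99)
  expect_equal(nrow(ev$losses), 0)
  expect_equal(nrow(ev$births), 0)

  tks <- list(make_tracklet(1, 0:100, cx = seq(0, 50, length.out = 101),
                            cy = seq(0, 50, length.out = 101)),
              make_tracklet(2, 110:150, cx = 52, cy = 51))
  ev <- find_events(tks, video_end = 200)
  expect_equal(nrow(ev$losses), 2)   # both end before the video does
  expect_equal(nrow(ev$births), 1)
  expect_equal(ev$births$track_id, 2L)
  expect_equal(ev$losses$x[ev$losses$track_id == 1], 50)
  expect_equal(ev$losses$y[ev$losses$track_id == 1], 50)
  expect_equal(ev$births$x, 52)
  expect_equal(ev$births$first_frame, 110L)
})

test_that("the forced-gap fixture yields exactly one loss and one birth, both bird 5", {
  s <- small_setup(n_birds = 12, duration_s = 30, seed = 4)
  dets <- render_setup(s)
  p <- tracker_params(gate_distance = 4 * median(dets$w), max_age = 10)
  dets2 <- drop_bird_window(dets, bird = 5, frames = 50:69)
  tk <- run_tracker(dets2, p)
  ev <- find_events(tk, video_end = 30 * s$sim$frame_rate - 1,
                    spawn_window = p$min_hits)
  expect_equal(nrow(ev$losses), 1)
  expect_equal(nrow(ev$births), 1)
  lost_tk <- tk[[which(vapply(tk, `[[`, integer(1), "track_id") ==
                         ev$losses$track_id)]]
  born_tk <- tk[[which(vapply(tk, `[[`, integer(1), "track_id") ==
                         ev$births$track_id)]]
  expect_equal(unique(dets2$truth_id[lost_tk$det_rows]), 5L)
  expect_equal(unique(dets2$truth_id[born_tk$det_rows]), 5L)
})

test_that("a single candidate within threshold merges; outside it the deletion rule applies", {
  losses <- data.frame(track_id = 1L, last_frame = 100L, x = 50, y = 50)
  births <- data.frame(track_id = 9L, first_frame = 110L, x = 52, y = 51,
                       length = 40L)
  m <- match_lost_new(losses, births, distance_threshold = 10, max_gap = 30)
  expect_equal(m$merges$lost_id, 1L)
  expect_equal(m$merges$new_id, 9L)
  expect_equal(m$merges$distance, sqrt(5))
  expect_equal(length(m$deletions), 0)

  far <- births; far$x <- 80; far$y <- 80; far$length <- 2L
  m2 <- match_lost_new(losses, far, distance_threshold = 10, max_gap = 30,
                       min_track_length = 5)
  expect_equal(nrow(m2$merges), 0)
  expect_equal(m2$deletions, 9L)

  # a birth before the loss, or beyond max_gap, is no candidate
  early <- births; early$first_frame <- 90L
  expect_equal(nrow(match_lost_new(losses, early, 10, 30)$merges), 0)
  late <- births; late$first_frame <- 140L
  expect_equal(nrow(match_lost_new(losses, late, 10, 30)$merges), 0)
})

test_that("pairing is the brute-force minimum-total-distance matching", {
  losses <- data.frame(track_id = c(1L, 2L), last_frame = c(10L, 10L),
                       x = c(0, 10), y = c(0, 0))
  births <- data.frame(track_id = c(11L, 12L), first_frame = c(15L, 15L),
                       x = c(1, 9), y = c(0, 0), length = c(50L, 50L))
  m <- match_lost_new(losses, births, distance_threshold = 5, max_gap = 30)
  expect_equal(nrow(m$merges), 2)
  got <- m$merges[order(m$merges$lost_id), ]
  expect_equal(got$new_id, c(11L, 12L))          # (0,0)-(1,0), (10,0)-(9,0)
  expect_equal(sum(got$distance), 2)             # brute-force minimum
  # the alternative pairing costs 9 + 9 = 18 > 2
})

test_that("random loss/birth clouds match at the exhaustive-pairing optimum", {
  set.seed(77)
  for (trial in 1:25) {
    nl <- sample(1:4, 1); nb <- sample(1:4, 1)
    losses <- data.frame(track_id = 1:nl, last_frame = 10L,
                         x = runif(nl, 0, 30), y = runif(nl, 0, 30))
    births <- data.frame(track_id = 100 + 1:nb, first_frame = 20L,
                         x = runif(nb, 0, 30), y = runif(nb, 0, 30),
                         length = 50L)
    th <- 20
    m <- match_lost_new(losses, births, th, max_gap = 30)
    # brute force: enumerate all injective pairings under the candidate rule,
    # maximize count then minimize total distance
    d <- sqrt(outer(births$x, losses$x, "-")^2 +
                outer(births$y, losses$y, "-")^2)
    feas <- d < th
    best_k <- -1; best_sum <- Inf
    assignments <- expand.grid(rep(list(0:nl), nb))
    for (r in seq_len(nrow(assignments))) {
      a <- as.integer(assignments[r, ])
      used <- a[a > 0]
      if (any(duplicated(used))) next
      if (any(a > 0 & !feas[cbind(seq_len(nb), pmax(a, 1))])) next
      k <- sum(a > 0); s <- sum(d[cbind(seq_len(nb), a)[a > 0, , drop = FALSE]])
      if (k > best_k || (k == best_k && s < best_sum - 1e-12)) {
        best_k <- k; best_sum <- s
      }
    }
    expect_equal(nrow(m$merges), best_k)
    if (best_k > 0) expect_equal(sum(m$merges$distance), best_sum,
                                 tolerance = 1e-9)
  }
})

test_that("merging concatenates chains under the root id and conserves observations", {
  tks <- list(make_tracklet(6, 0:99, cx = seq(0, 20, length.out = 100),
                            cy = 0),
              make_tracklet(126, 120:199, cx = seq(21, 40, length.out = 80),
                            cy = 0))
  losses <- data.frame(track_id = 6L, last_frame = 99L, x = 20, y = 0)
  births <- data.frame(track_id = 126L, first_frame = 120L, x = 21, y = 0,
                       length = 80L)
  m <- match_lost_new(losses, births, distance_threshold = 5, max_gap = 30)
  trajs <- merge_tracklets(tks, m)
  expect_equal(length(trajs), 1)
  expect_equal(trajs[[1]]$bird_id, 6L)
  expect_equal(length(trajs[[1]]$frames), 180)
  expect_equal(trajs[[1]]$source_ids, c(6L, 126L))
  expect_sorted_increasing(trajs[[1]]$frames)

  # empty mapping: trajectories are the tracklets themselves
  empty_map <- match_lost_new(losses[0, ], births[0, ], 5, 30)
  idt <- merge_tracklets(tks, empty_map)
  expect_equal(length(idt), 2)
  expect_equal(sum(lengths(lapply(idt, `[[`, "frames"))), 180)

  # overlapping chain members are a mapping-integrity error
  bad <- make_tracklet(126, 90:199, cx = 21, cy = 0)
  expect_error(merge_tracklets(list(tks[[1]], bad), m), "overlap")
})

test_that("chains compose transitively to a single root", {
  tks <- list(make_tracklet(1, 0:9, cx = 0, cy = 0),
              make_tracklet(2, 15:24, cx = 1, cy = 0),
              make_tracklet(3, 30:39, cx = 2, cy = 0))
  losses <- data.frame(track_id = c(1L, 2L), last_frame = c(9L, 24L),
                       x = c(0, 1), y = c(0, 0))
  births <- data.frame(track_id = c(2L, 3L), first_frame = c(15L, 30L),
                       x = c(1, 2), y = c(0, 0), length = c(10L, 10L))
  m <- match_lost_new(losses, births, distance_threshold = 5, max_gap = 30)
  expect_equal(nrow(m$merges), 2)
  trajs <- merge_tracklets(tks, m)
  expect_equal(length(trajs), 1)
  expect_equal(trajs[[1]]$bird_id, 1L)
  expect_equal(trajs[[1]]$source_ids, 1:3)
})

test_that("the merged forced-gap fixture restores 12 birds and their point counts", {
  s <- small_setup(n_birds = 12, duration_s = 30, seed = 4)
  dets <- render_setup(s)
  n_frames <- 30 * s$sim$frame_rate
  p <- tracker_params(gate_distance = 4 * median(dets$w), max_age = 10)
  dets2 <- drop_bird_window(dets, bird = 5, frames = 50:69)
  fit <- track_pen(dets2, s$cfg, params = p, n_frames = n_frames)
  expect_equal(length(fit$trajectories), 12)
  expect_equal(nrow(fit$mapping$merges), 1)
  # conservation: merged points = total tracklet points; only bird 5 short
  n_pts <- vapply(fit$trajectories, function(t) length(t$frames), integer(1))
  expect_equal(sum(n_pts),
               sum(vapply(fit$tracklets, function(t) length(t$frames),
                          integer(1))))
  expect_equal(sort(n_pts, decreasing = TRUE)[1:11], rep(n_frames, 11))
  merged <- Filter(function(t) length(t$source_ids) == 2, fit$trajectories)
  expect_equal(length(merged), 1)
  expect_equal(length(merged[[1]]$frames), n_frames - 20)
})

test_that("appearance percentage counts observed frames", {
  tr <- new_trajectory(1, frames = 0:899, cx = 0, cy = 0)
  expect_equal(appearance_percentage(tr, 900), 100)
  half <- new_trajectory(1, frames = seq(0, 898, by = 2), cx = 0, cy = 0)
  expect_equal(appearance_percentage(half, 900), 50)
})

test_that("merge count is non-decreasing in the distance threshold", {
  set.seed(55)
  tks <- lapply(1:10, function(i) {
    start <- sample(0:50, 1)
    make_tracklet(i, start:(start + 20), cx = runif(1, 0, 100),
                  cy = runif(1, 0, 100))
  })
  sweep <- sweep_threshold(tks, video_end = 200,
                           thresholds = c(1, 5, 10, 25, 50, 100, 200),
                           max_gap = 60)
  expect_true(all(diff(sweep$n_merges) >= 0))
})

test_that("merging never decreases a bird's distance or appearance", {
  s <- small_setup(n_birds = 10, duration_s = 60, seed = 12)
  noise <- noise_config(base_miss_prob = 0.03, occlusion_dropout_prob = 0.4,
                        false_pos_rate = 0.05, jitter_sd_cm = 0.1,
                        gap_extension_prob = 0.75)
  dets <- render_setup(s, noise)
  n_frames <- 60 * s$sim$frame_rate
  # max_age of one sampling interval keeps merged fragments on disjoint
  # grid cells, so monotonicity is exact
  p <- tracker_params(gate_distance = 4 * median(dets$w), max_age = 5)
  fit <- track_pen(dets, s$cfg, params = p, n_frames = n_frames)
  by_id <- stats::setNames(fit$tracklets,
                           vapply(fit$tracklets, `[[`, integer(1),
                                  "track_id"))
  n_checked <- 0
  for (traj in fit$trajectories) {
    after <- bird_summary(traj, fit$calib, s$cfg, n_frames)
    for (src in as.character(traj$source_ids)) {
      t <- by_id[[src]]
      frag <- new_trajectory(t$track_id, t$frames, t$cx, t$cy, t$w, t$h)
      pre <- bird_summary(frag, fit$calib, s$cfg, n_frames)
      expect_gte(after$total_distance + 1e-9, pre$total_distance)
      expect_gte(after$appearance_pct + 1e-9, pre$appearance_pct)
      n_checked <- n_checked + 1
    }
  }
  expect_gte(nrow(fit$mapping$merges), 1)  # the regime really merged
  expect_gt(n_checked, length(fit$trajectories))
})
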