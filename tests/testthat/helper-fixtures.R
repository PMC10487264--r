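# shared fixture builders and independent oracles

# a small pen setup: 500 x 750 px image of the 100 x 150 cm pen
small_setup <- function(n_birds = 3, duration_s = 60, seed = 7,
                        frame_rate = 5, deadband = 0, ...) {
  cfg <- run_config(frame_rate = frame_rate, deadband = deadband,
                    image_width_px = 500, image_height_px = 750, ...)
  sim <- sim_config(n_birds = n_birds, duration_s = duration_s,
                    frame_rate = frame_rate, seed = seed)
  calib <- calibrate_pen(100, 150, 500, 750)
  truth <- simulate_motion(sim)
  list(cfg = cfg, sim = sim, calib = calib, truth = truth)
}

render_setup <- function(s, noise = no_noise(), seed = s$sim$seed) {
  render_detections(s$truth, noise, s$calib, seed = seed,
                    bird_radius_cm = s$sim$bird_radius_cm,
                    pen_width_cm = s$sim$pen_width_cm,
                    pen_height_cm = s$sim$pen_height_cm)
}

# exhaustive-permutation oracle for the optimal assignment total cost:
# minimum over all one-to-one matchings of all rows (n <= m) or all
# columns (m < n) of a cost matrix
perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  }
  out
}

brute_force_min_cost <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n <= m) {
    best <- Inf
    for (p in perms(seq_len(m))) {
      best <- min(best, sum(cost[cbind(seq_len(n), p[seq_len(n)])]))
    }
  } else {
    best <- brute_force_min_cost(t(cost))
  }
  best
}

# build a detection table directly from ground truth (no corruption),
# then knock out one bird's detections over a frame window
drop_bird_window <- function(dets, bird, frames) {
  dets[!(dets$truth_id == bird & dets$frame %in% frames), , drop = FALSE]
}

expect_sorted_increasing <- function(x) {
  expect_true(all(diff(x) > 0))
}
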