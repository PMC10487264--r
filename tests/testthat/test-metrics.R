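test_that("box IoU handles identity, disjoint and partial overlap", {
  a <- list(x = 0, y = 0, w = 10, h = 10)
  expect_equal(box_iou(a, a), 1)
  expect_equal(box_iou(a, list(x = 20, y = 20, w = 10, h = 10)), 0)
  # half-overlapping squares: inter 50, union 150
  expect_equal(box_iou(a, list(x = 5, y = 0, w = 10, h = 10)), 50 / 150)
})

test_that("perfect and absent detections give the boundary match counts", {
  s <- small_setup(n_birds = 6, duration_s = 10, seed = 2)
  dets <- render_setup(s)
  res <- match_detections(dets, s$truth, s$calib)
  expect_equal(res$fp, 0)
  expect_equal(res$fn, 0)
  expect_equal(res$tp, nrow(s$truth))
  none <- match_detections(dets[0, ], s$truth, s$calib)
  expect_equal(none$tp, 0)
  expect_equal(none$fn, nrow(s$truth))
})

test_that("greedy matching counts agree with brute force on a constructed overlap case", {
  # one frame, 5 truth boxes on a line, 5 detections with varying shifts
  truth <- data.frame(bird_id = 1:5, frame = 0L,
                      x_cm = c(10, 30, 50, 70, 90), y_cm = 50)
  cal <- calibrate_pen(100, 100, 100, 100)
  r <- 5  # boxes 10 x 10
  shifts <- c(0, 2, 4, 9, 20)      # IoUs 1, .67, .43, .05, 0
  dets <- data.frame(frame = 0L, x = truth$x_cm - r + shifts,
                     y = truth$y_cm - r, w = 10, h = 10,
                     conf = c(0.9, 0.8, 0.95, 0.7, 0.6))
  res <- match_detections(dets, truth, cal, iou_threshold = 0.4,
                          bird_radius_cm = r)
  # brute force: count boxes whose best IoU >= 0.4 (boxes are well separated,
  # so greedy and optimal agree here)
  ious <- 1 - shifts / 10
  ious <- pmax(0, (10 - shifts) / (10 + shifts))
  expect_equal(res$tp, sum(ious >= 0.4))
  expect_equal(res$fp, sum(ious < 0.4))
  expect_equal(res$fn, sum(ious < 0.4))
})

test_that("precision follows TP/(TP+FP) with the no-prediction convention", {
  mk <- function(tp, fp) structure(list(tp = tp, fp = fp, fn = 0,
                                        iou_threshold = 0.5),
                                   class = "detection_match")
  expect_equal(detection_precision(mk(9, 1)), 0.9)
  expect_equal(detection_precision(mk(0, 5)), 0)
  expect_equal(detection_precision(mk(7, 0)), 1)
  expect_equal(detection_precision(mk(0, 0)), 1)
})

test_that("average precision integrates the precision-recall curve; mAP = AP for one class", {
  s <- small_setup(n_birds = 6, duration_s = 10, seed = 2)
  dets <- render_setup(s)
  ap <- average_precision(dets, s$truth, s$calib)
  expect_equal(ap$ap, 1.0)
  expect_equal(ap$map, ap$ap)
  # only false positives: AP = 0
  junk <- dets
  junk$x <- junk$x + 10000   # displace every box clear of the pen
  expect_equal(average_precision(junk, s$truth, s$calib)$ap, 0)
  expect_error(average_precision(dets, s$truth[0, ], s$calib), "ground truth")
})

test_that("AP equals the hand-computed step integral on a constructed ranking", {
  # single frame, 5 truth boxes; 10 detections ranked by confidence with
  # TP/FP pattern T F T T F F T F F F after IoU matching
  cal <- calibrate_pen(100, 100, 100, 100)
  truth <- data.frame(bird_id = 1:5, frame = 0L,
                      x_cm = seq(10, 90, by = 20), y_cm = 50)
  tp_x <- truth$x_cm - 5                     # exact hits
  fp_x <- truth$x_cm - 5                     # duplicates -> FP after claiming
  ord_conf <- seq(1, 0.1, by = -0.1)
  pat <- c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)
  xs <- numeric(10); used <- 0
  for (i in 1:10) {
    if (pat[i]) { used <- used + 1; xs[i] <- tp_x[used] }
    else xs[i] <- fp_x[max(used, 1)]         # re-hit an already claimed box
  }
  dets <- data.frame(frame = 0L, x = xs, y = 45, w = 10, h = 10,
                     conf = ord_conf)
  got <- average_precision(dets, truth, cal, iou_threshold = 0.5,
                           bird_radius_cm = 5)
  # hand-computed all-point interpolation:
  # cum TP 1,1,2,3,3,3,4,4,4,4 ; recall k/5 ; precision 1,.5,.67,.75,.6,.5,
  # .571,.5,.444,.4 ; envelope at recall steps: .75 (r .2,.4,.6), .571 (r .8)
  expected <- 0.2 * 1 + 0.2 * (3 / 4) + 0.2 * (3 / 4) + 0.2 * (4 / 7)
  expect_equal(got$ap, expected, tolerance = 1e-12)
})

test_that("R squared reproduces hand arithmetic and its edge cases", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  a <- c(2, 4, 9, 1)
  expect_equal(r_squared(a, rep(mean(a), 4)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_error(r_squared(1:3, 1:4), "equal length")
})

test_that("R squared is invariant under common affine rescaling", {
  set.seed(3)
  y <- rnorm(50); yhat <- y + rnorm(50, 0, 0.3)
  base <- r_squared(y, yhat)
  expect_equal(r_squared(10 * y + 4, 10 * yhat + 4), base, tolerance = 1e-12)
  expect_equal(r_squared(-2 * y + 1, -2 * yhat + 1), base, tolerance = 1e-12)
})

test_that("improving a detection's overlap never decreases TP", {
  cal <- calibrate_pen(100, 100, 100, 100)
  truth <- data.frame(bird_id = 1, frame = 0L, x_cm = 50, y_cm = 50)
  for (shift in c(9, 6, 4, 2, 0)) {
    dets <- data.frame(frame = 0L, x = 45 + shift, y = 45, w = 10, h = 10,
                       conf = 0.9)
    res <- match_detections(dets, truth, cal, 0.5, bird_radius_cm = 5)
    if (shift <= 2) expect_equal(res$tp, 1) else expect_equal(res$tp, 0)
  }
})

test_that("ID-recovery scoring is vacuously perfect without merges and exact on fixtures", {
  s <- small_setup(n_birds = 6, duration_s = 30, seed = 6)
  dets <- render_setup(s)
  fit <- track_pen(dets, s$cfg)
  m <- id_recovery_metrics(fit$trajectories, fit$tracklets, dets$truth_id,
                           s$truth, fit$calib, s$cfg)
  expect_equal(m$n_merges, 0)
  expect_equal(m$merge_accuracy, 1)
  expect_equal(m$distance_error_pct, 0, tolerance = 1e-9)

  # forced gap: exactly one known-correct merge
  p <- tracker_params(gate_distance = 4 * median(dets$w), max_age = 10)
  dets2 <- drop_bird_window(dets, bird = 3, frames = 60:79)
  fit2 <- track_pen(dets2, s$cfg, params = p,
                    n_frames = 30 * s$sim$frame_rate)
  m2 <- id_recovery_metrics(fit2$trajectories, fit2$tracklets,
                            dets2$truth_id)
  expect_equal(m2$n_merges, 1)
  expect_equal(m2$merge_accuracy, 1)
})

test_that("an adversarial birth nearer the wrong loss is scored as an error", {
  # loss A at (0,0), loss B at (6,0); the bird behind B reappears at (1,0):
  # matching must pair it with A by distance, which truth says is wrong
  mk <- function(id, frames, cx, truth) {
    structure(list(track_id = id, frames = frames, cx = rep(cx,
                                                            length(frames)),
                   cy = rep(0, length(frames)),
                   w = rep(2, length(frames)), h = rep(2, length(frames)),
                   conf = rep(1, length(frames)),
                   det_rows = rep(truth, length(frames)),
                   status = "confirmed", first_frame = frames[1],
                   last_frame = frames[length(frames)]),
              class = "tracklet")
  }
  # det_rows here index a fake truth-id lookup: row i -> truth id
  truth_ids <- c(101L, 202L, 202L)
  tks <- list(mk(1L, 0:9, cx = 0, truth = 1),      # bird 101, lost
              mk(2L, 0:9, cx = 6, truth = 2),      # bird 202, lost
              mk(3L, 15:40, cx = 1, truth = 3))    # bird 202 reappearing
  ev <- find_events(tks, video_end = 60, spawn_window = 3)
  map <- match_lost_new(ev$losses, ev$births, distance_threshold = 4,
                        max_gap = 30)
  expect_equal(map$merges$lost_id, 1L)   # distance rule picks the wrong loss
  trajs <- merge_tracklets(tks, map)
  m <- id_recovery_metrics(trajs, tks, truth_ids)
  expect_equal(m$n_merges, 1)
  expect_equal(m$merge_accuracy, 0)
})
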