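test_that("speeds are calibrated displacement over elapsed time", {
  # 3-4-5 triangle: 50 px at 10 px/cm over 15 s -> 1200 cm/h
  tr <- data.frame(track_id = 0L, frame = 0:1, x_px = c(0, 30),
                   y_px = c(0, 40), observed = TRUE)
  mv <- compute_speeds(tr, px_per_cm = 10, frame_interval_s = 15)
  expect_equal(mv$displacement_cm, 5)
  expect_equal(mv$speed_cm_per_h, 1200)
  expect_equal(mv$category, "fast")
  # stationary track: all resting at speed 0
  trs <- data.frame(track_id = 0L, frame = 0:5, x_px = 3, y_px = 3,
                    observed = TRUE)
  mvs <- compute_speeds(trs, 10, 15)
  expect_true(all(mvs$speed_cm_per_h == 0))
  expect_true(all(mvs$category == "resting"))
  # gap spanning: frames 0 and 4, 10 px apart -> 60 s, 60 cm/h
  trg <- data.frame(track_id = 0L, frame = c(0L, 4L), x_px = c(0, 10),
                    y_px = 0, observed = TRUE)
  mvg <- compute_speeds(trg, 10, 15)
  expect_equal(mvg$elapsed_s, 60)
  expect_equal(mvg$speed_cm_per_h, 60)
  # speed identity holds to 1e-9 relative
  expect_equal(mvg$speed_cm_per_h,
               mvg$displacement_cm / (mvg$elapsed_s / 3600),
               tolerance = 1e-9)
  # fewer than two observed entries -> no records
  expect_equal(nrow(compute_speeds(trg[1, ], 10, 15)), 0L)
  expect_error(compute_speeds(tr, 0, 15), "px_per_cm")
})

test_that("the category partition is total with the documented boundaries", {
  eps <- 1e-6
  expect_equal(classify_speed(c(0, 0.39, 0.4 - eps)), rep("resting", 3))
  expect_equal(classify_speed(c(0.4, 2, 4)), rep("slow", 3))
  expect_equal(classify_speed(c(4 + eps, 4.0001, 100)), rep("fast", 3))
  set.seed(6)
  sp <- c(runif(500, 0, 10), 0, 0.4, 4)
  cats <- classify_speed(sp)
  expect_true(all(cats %in% c("resting", "slow", "fast")))
  expect_error(classify_speed(-0.1), "non-negative")
})

test_that("category tallies conserve the number of intervals", {
  expect_equal(nrow(tally_categories(
    data.frame(flume_id = character(0), category = character(0)))), 0L)
  rec <- data.frame(flume_id = "A", category = rep("fast", 10))
  tc <- tally_categories(rec)
  expect_equal(tc$fast, 10L)
  expect_equal(tc$resting + tc$slow, 0L)
  set.seed(8)
  rec2 <- data.frame(flume_id = sample(c("A", "B"), 200, TRUE),
                     category = sample(c("resting", "slow", "fast"),
                                       200, TRUE))
  tc2 <- tally_categories(rec2)
  expect_equal(sum(tc2$resting + tc2$slow + tc2$fast), 200L)
  expect_equal(tc2$total, tc2$resting + tc2$slow + tc2$fast)
})

test_that("noiseless tracking recovers ground-truth state tallies exactly", {
  sc <- scene_config(n_grazers = 4, duration_s = 1800, px_per_cm = 10)
  tr <- simulate_trajectories(sc, behaviour_model(), seed = 23)
  tdet <- truth_detections(tr)
  # perfect single-grazer tracks built from the truth itself
  tk <- data.frame(track_id = tdet$grazer_id, frame = tdet$frame,
                   x_px = tdet$x_px, y_px = tdet$y_px, observed = TRUE)
  mv <- compute_speeds(tk, sc$px_per_cm, sc$frame_interval_s,
                       flume_id = "F1")
  iv <- truth_intervals(tr)
  expect_equal(nrow(mv), nrow(iv))
  got <- table(factor(mv$category, c("resting", "slow", "fast")))
  want <- table(factor(iv$state, c("resting", "slow", "fast")))
  expect_equal(as.vector(got), as.vector(want))
  tc <- tally_categories(mv)
  expect_equal(tc$total, nrow(iv))
})

test_that("image-based classification recovers latent states at >= 95%", {
  # boundary-resolvable profile: 10-min frames at 20 px/cm make the
  # resting/slow boundary ~1.3 px, far above centroid noise
  sc <- scene_config(flume_length_cm = 24, flume_width_cm = 8,
                     tile_cols = 10, tile_rows = 3,
                     n_grazers = 2, duration_s = 600 * 60,
                     frame_interval_s = 600, px_per_cm = 20,
                     marker_radius_cm = 0.2)
  tr <- simulate_trajectories(sc, behaviour_model(), seed = 37,
                              init_positions = cbind(c(6, 18), c(4, 4)))
  rend <- render_frames(tr)
  dets <- detect_sequence(rend$frames, colour_spec(sc$marker_rgb),
                          expected_area_px = pi * (sc$marker_radius_cm *
                                                     sc$px_per_cm)^2)
  init <- as.matrix(truth_detections(tr)[tr$trajectories$frame == 0,
                                         c("x_px", "y_px")])
  tk <- link_sequence(dets, link_params(n_expected = 2, max_step_px = 50),
                      initial_positions = init, n_frames = sc$n_frames)
  mv <- compute_speeds(tk, sc$px_per_cm, sc$frame_interval_s)
  iv <- truth_intervals(tr)
  merged <- merge(mv, iv, by.x = c("track_id", "frame_from"),
                  by.y = c("grazer_id", "frame_from"))
  expect_gt(nrow(merged), 100L)
  expect_gte(mean(merged$category == merged$state), 0.95)
})
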