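test_that("single track and detection within the gate are matched", {
  tp <- data.frame(track_id = 0L, x_px = 5, y_px = 5)
  dets <- data.frame(x_px = 6, y_px = 5)
  a <- assign_frame(tp, dets, link_params(n_expected = 1, max_step_px = 5))
  expect_equal(nrow(a$matches), 1L)
  expect_equal(a$matches$cost, 1)
  expect_length(a$unmatched_tracks, 0)
})

test_that("assignment is globally optimal, not greedy", {
  tp <- data.frame(track_id = 0:1, x_px = c(0, 10), y_px = c(0, 0))
  dets <- data.frame(x_px = c(6, 11), y_px = c(0, 0))
  a <- assign_frame(tp, dets, link_params(n_expected = 2, max_step_px = 100))
  a <- a$matches[order(a$matches$track_id), ]
  expect_equal(a$detection, c(1L, 2L))     # (0,0)->(6,0), (10,0)->(11,0)
  expect_equal(sum(a$cost), 7)             # not the greedy 1 + 10 = 11
})

test_that("with fewer detections than tracks exactly one track gaps, optimally", {
  set.seed(91)
  for (k in 1:5) {
    tp <- data.frame(track_id = 0:2, x_px = runif(3, 0, 50),
                     y_px = runif(3, 0, 50))
    dets <- data.frame(x_px = runif(2, 0, 50), y_px = runif(2, 0, 50))
    a <- assign_frame(tp, dets, link_params(n_expected = 3,
                                            max_step_px = 1e6))
    expect_equal(nrow(a$matches), 2L)
    expect_length(a$unmatched_tracks, 1L)
    cost <- sqrt(outer(tp$x_px, dets$x_px, `-`)^2 +
                   outer(tp$y_px, dets$y_px, `-`)^2)
    want <- oracle_assignment(cost, 1e6)
    expect_equal(sum(a$matches$cost), want$cost, tolerance = 1e-9)
  }
})

test_that("per-frame assignment cost equals the exhaustive optimum with gating", {
  set.seed(17)
  for (k in 1:20) {
    nt <- sample(1:5, 1)
    nd <- sample(1:5, 1)
    tp <- data.frame(track_id = seq_len(nt) - 1L,
                     x_px = runif(nt, 0, 30), y_px = runif(nt, 0, 30))
    dets <- data.frame(x_px = runif(nd, 0, 30), y_px = runif(nd, 0, 30))
    gate <- runif(1, 5, 25)
    a <- assign_frame(tp, dets, link_params(n_expected = nt,
                                            max_step_px = gate))
    cost <- sqrt(outer(tp$x_px, dets$x_px, `-`)^2 +
                   outer(tp$y_px, dets$y_px, `-`)^2)
    want <- oracle_assignment(cost, gate)
    expect_equal(nrow(a$matches), want$n_match)
    expect_equal(sum(a$matches$cost), want$cost, tolerance = 1e-9)
    # no detection used twice
    expect_false(anyDuplicated(a$matches$detection) > 0)
  }
})

test_that("a static object links into one fully observed track", {
  dets <- data.frame(frame = 0:9, x_px = 5, y_px = 7)
  tk <- link_sequence(dets, link_params(n_expected = 1, max_step_px = 3))
  expect_equal(sum(tk$observed), 10L)
  expect_equal(unique(tk$track_id), 0L)
  expect_true(all(tk$x_px == 5))
})

test_that("a deleted detection creates a gap that closes with the same id", {
  dets <- data.frame(frame = 0:9, x_px = (0:9) * 2, y_px = 0)
  dets <- dets[dets$frame != 5L, ]
  tk <- link_sequence(dets, link_params(n_expected = 1, max_step_px = 5),
                      n_frames = 10)
  expect_equal(unique(tk$track_id), 0L)
  expect_false(tk$observed[tk$frame == 5])
  expect_true(is.na(tk$x_px[tk$frame == 5]))  # gaps carry no coordinates
  expect_true(tk$observed[tk$frame == 6])
  expect_equal(tk$x_px[tk$frame == 6], 12)
})

test_that("no detections at all leaves tracks as initial positions plus gaps", {
  dets <- data.frame(frame = integer(0), x_px = numeric(0),
                     y_px = numeric(0))
  init <- cbind(c(1, 5), c(1, 5))
  tk <- link_sequence(dets, link_params(n_expected = 2, max_step_px = 3),
                      initial_positions = init, n_frames = 4)
  expect_equal(nrow(tk), 8L)
  expect_false(any(tk$observed))
  expect_equal(attr(tk, "initial_positions"), init)
})

test_that("non-crossing synthetic scenes are tracked with perfect identity", {
  sc <- scene_config(n_grazers = 8, duration_s = 7200, px_per_cm = 10)
  tr <- simulate_trajectories(sc, sluggish_behaviour(), seed = 101,
                              init_positions = spaced_positions(8, sc))
  tdet <- truth_detections(tr)
  # precondition: minimum pairwise distance exceeds twice the maximal
  # per-interval displacement
  max_step_px <- 4.6 * sc$frame_interval_s / 3600 * sc$px_per_cm
  min_sep <- min(vapply(unique(tdet$frame), function(f) {
    d <- tdet[tdet$frame == f, ]
    min(stats::dist(cbind(d$x_px, d$y_px)))
  }, numeric(1)))
  expect_gt(min_sep, 2 * max_step_px)
  init <- as.matrix(tdet[tdet$frame == 0, c("x_px", "y_px")][
    order(tdet$grazer_id[tdet$frame == 0]), ])
  tk <- link_sequence(tdet[, c("frame", "x_px", "y_px")],
                      link_params(n_expected = 8,
                                  max_step_px = 3 * max_step_px),
                      initial_positions = init, n_frames = sc$n_frames)
  expect_true(all(tk$observed))
  merged <- merge(as.data.frame(tk), tdet,
                  by.x = c("track_id", "frame"),
                  by.y = c("grazer_id", "frame"))
  agree <- mean(abs(merged$x_px.x - merged$x_px.y) < 1e-9 &
                  abs(merged$y_px.x - merged$y_px.y) < 1e-9)
  expect_equal(agree, 1.0)
})
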