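test_that("config validation rejects degenerate scenes and models", {
  expect_error(scene_config(px_per_cm = 0), "px_per_cm")
  expect_error(scene_config(frame_interval_s = 0), "frame_interval_s")
  expect_error(scene_config(tile_cols = 40), "does not fit")
  expect_error(scene_config(marker_rgb = c(60, 90, 40)), "differ")
  expect_error(behaviour_model(matrix(1 / 2, 3, 3)), "row-stochastic")
  expect_error(behaviour_model(speed_ranges = list(resting = c(0, 0.5),
                                                   slow = c(0.6, 3.5),
                                                   fast = c(5, 10))),
               "resting")
})

test_that("an absorbing rest state with zero speed freezes all grazers", {
  sc <- scene_config(n_grazers = 4, duration_s = 300, px_per_cm = 5)
  bm <- behaviour_model(diag(3),
                        speed_ranges = list(resting = c(0, 0),
                                            slow = c(0.5, 3), fast = c(5, 8)))
  tr <- simulate_trajectories(sc, bm, seed = 11, init_state = "resting")
  d <- tr$trajectories
  expect_true(all(d$state == "resting"))
  for (g in unique(d$grazer_id)) {
    dg <- d[d$grazer_id == g, ]
    expect_equal(diff(range(dg$x_cm)), 0)
    expect_equal(diff(range(dg$y_cm)), 0)
  }
})

test_that("zero duration yields a single frame and no intervals", {
  sc <- scene_config(n_grazers = 3, duration_s = 0)
  tr <- simulate_trajectories(sc, behaviour_model(), seed = 2)
  expect_equal(sc$n_frames, 1L)
  expect_equal(nrow(tr$trajectories), 3L)
  expect_equal(nrow(truth_intervals(tr)), 0L)
})

test_that("state frequencies follow the chain's stationary distribution", {
  # rows all equal to pi make the chain iid with stationary pi
  pi0 <- c(0.5, 0.3, 0.2)
  P <- matrix(rep(pi0, each = 3), 3)
  bm <- behaviour_model(P)
  n_int <- 10000L
  sc <- scene_config(n_grazers = 1, duration_s = 15 * n_int,
                     px_per_cm = 2)
  tr <- simulate_trajectories(sc, bm, seed = 5)
  iv <- truth_intervals(tr)
  expect_equal(nrow(iv), n_int)
  freq <- table(factor(iv$state, c("resting", "slow", "fast"))) / n_int
  se <- sqrt(pi0 * (1 - pi0) / n_int)
  expect_true(all(abs(as.numeric(freq) - pi0) <= 3 * se))
})

test_that("per-interval displacement always lies in the generating state's band", {
  sc <- scene_config(n_grazers = 3, duration_s = 3000, px_per_cm = 5)
  tr <- simulate_trajectories(sc, behaviour_model(), seed = 9)
  iv <- truth_intervals(tr)
  band <- list(resting = c(0, 0.4), slow = c(0.4, 4), fast = c(4, Inf))
  for (st in names(band)) {
    sp <- iv$speed_cm_per_h[iv$state == st]
    expect_true(all(sp >= band[[st]][1] - 1e-9))
    expect_true(all(sp < band[[st]][2] + 1e-9))
  }
  expect_true(all(tr$trajectories$x_cm >= 0 &
                    tr$trajectories$x_cm <= sc$flume_length_cm))
  expect_true(all(tr$trajectories$y_cm >= 0 &
                    tr$trajectories$y_cm <= sc$flume_width_cm))
})

test_that("simulation is bitwise deterministic under a fixed seed", {
  sc <- scene_config(n_grazers = 5, duration_s = 600)
  a <- simulate_trajectories(sc, behaviour_model(), seed = 42)
  b <- simulate_trajectories(sc, behaviour_model(), seed = 42)
  expect_identical(a$trajectories, b$trajectories)
  c <- simulate_trajectories(sc, behaviour_model(), seed = 43)
  expect_false(identical(b$trajectories, c$trajectories))
})

test_that("grazed masks are cumulative and equal the rendered bare area", {
  sc <- scene_config(n_grazers = 3, duration_s = 300, px_per_cm = 6)
  tr <- simulate_trajectories(sc, behaviour_model(), seed = 3)
  rend <- render_frames(tr, draw_markers = FALSE)
  for (f in 2:length(rend$masks)) {
    expect_true(all(rend$masks[[f]] >= rend$masks[[f - 1]]))
  }
  # bare-coloured pixels inside the tile mask are exactly the mask
  final <- rend$frames[[length(rend$frames)]]
  bare <- final[, , 1] == sc$bare_rgb[1] & final[, , 2] == sc$bare_rgb[2] &
    final[, , 3] == sc$bare_rgb[3]
  expect_equal(sum(bare & rend$tile_mask),
               rend$grazed_px[length(rend$grazed_px)])
  expect_identical(bare & rend$tile_mask,
                   rend$masks[[length(rend$masks)]])
})

test_that("a stationary grazer's footprint matches a per-pixel distance oracle", {
  sc <- scene_config(n_grazers = 1, duration_s = 60, px_per_cm = 10,
                     mouth_radius_cm = 0.4)
  bm <- behaviour_model(diag(3),
                        speed_ranges = list(resting = c(0, 0),
                                            slow = c(0.5, 3), fast = c(5, 8)))
  pos <- matrix(c(31, 4), 1)  # tile interior, flume centre
  tr <- simulate_trajectories(sc, bm, seed = 1, init_state = "resting",
                              init_positions = pos)
  rend <- render_frames(tr, draw_markers = FALSE)
  tiles <- rend$tile_mask
  s <- sc$px_per_cm
  xc <- (col(tiles) - 0.5) / s
  yc <- (row(tiles) - 0.5) / s
  oracle <- sum(tiles & (xc - 31)^2 + (yc - 4)^2 <= sc$mouth_radius_cm^2)
  expect_equal(rend$grazed_px[length(rend$grazed_px)], oracle)
})

test_that("markers render exactly at the target colour at disc centre", {
  sc <- scene_config(n_grazers = 1, duration_s = 0, px_per_cm = 10)
  bm <- behaviour_model()
  tr <- simulate_trajectories(sc, bm, seed = 8,
                              init_positions = matrix(c(31, 4), 1))
  rend <- render_frames(tr)
  img <- rend$frames[[1]]
  i <- round(4 * sc$px_per_cm + 0.5)
  j <- round(31 * sc$px_per_cm + 0.5)
  expect_equal(as.numeric(img[i, j, ]), sc$marker_rgb)
})

test_that("a grazer-free scene grazes nothing", {
  sc <- scene_config(n_grazers = 0, duration_s = 60, px_per_cm = 5)
  tr <- simulate_trajectories(sc, behaviour_model(), seed = 4)
  rend <- render_frames(tr)
  expect_true(all(rend$grazed_px == 0L))
})

test_that("assay tables are deterministic and follow their distributions", {
  cfg <- assay_config()
  a <- generate_assay_tables(cfg, seed = 21)
  b <- generate_assay_tables(cfg, seed = 21)
  expect_identical(a$elemental, b$elemental)
  expect_identical(a$pigments, b$pigments)
  # noiseless construction: single group with unit abundance reproduces
  # the ratio row exactly
  F <- example_ratio_matrix("oligotrophic")
  A1 <- matrix(c(1, 0), 1, dimnames = list("s1", rownames(F)))
  S1 <- synth_pigment_samples(A1, F, noise = 0)
  expect_equal(as.numeric(S1), as.numeric(F["diatoms", ]))
  # drawn C:P is consistent with the C and P masses
  expect_equal(molar_cp(a$elemental$C_mass_ug, a$elemental$P_mass_ug),
               a$elemental$cp_true)
  expect_error(
    assay_config(elemental = transform(default_elemental_config(),
                                       cp_sd = -1)),
    "SDs")
})

test_that("regenerated phosphorus-poor C:P means centre on the configured 316", {
  cfg <- assay_config()
  n_rep <- 1000L
  means <- vapply(seq_len(n_rep), function(k) {
    tab <- generate_assay_tables(cfg, seed = 100000L + k)$elemental
    mean(tab$cp_true[tab$treatment == "P-" & tab$timepoint == "start"])
  }, numeric(1))
  se <- 68 / sqrt(6 * n_rep)
  expect_lt(abs(mean(means) - 316), 3 * se)
})
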