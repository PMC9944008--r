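#' Scene configuration for the synthetic flume
#'
#' Describes the physical layout of one experimental flume as seen by an
#' overhead camera: flume footprint, the grid of ceramic substrate tiles,
#' the pixel scale, the frame interval of the time-lapse, and the colours
#' used to render biofilm, bare tile and the pink shell markers.
#'
#' Defaults mirror the mesocosm set-up: a 62 x 8 cm flume holding 30 tiles
#' of 2.3 cm side (3 rows x 10 columns, 158.7 cm2 of substrate), frames
#' every 15 s, and eight marked grazers. The default desk-scale duration is
#' 2 h (480 frame intervals) so that full pipelines stay cheap; pass
#' `duration_s = 14 * 24 * 3600` for an experiment-scale run.
#'
#' @param flume_length_cm,flume_width_cm flume footprint in cm.
#' @param tile_side_cm side of one square substrate tile (cm).
#' @param tile_rows,tile_cols tile grid layout (rows span the flume width).
#' @param removed_tiles integer indices (1-based, row-major) of tiles taken
#'   out before the run; rendered as bare tray and excluded from the
#'   substrate area.
#' @param px_per_cm isotropic pixel scale of the rendered frames.
#' @param frame_interval_s time between consecutive frames (s).
#' @param duration_s total recorded duration (s); the number of frames is
#'   `floor(duration_s / frame_interval_s) + 1`.
#' @param n_grazers number of colour-marked grazers.
#' @param marker_rgb,biofilm_rgb,bare_rgb,tray_rgb render colours
#'   (length-3, 0-255). The marker colour must differ from both substrate
#'   colours.
#' @param marker_radius_cm radius of the painted shell marker (cm).
#' @param mouth_radius_cm radius of the grazing footprint around each
#'   visited position (cm).
#' @param seed optional default seed consumed by [simulate_trajectories()].
#'
#' @return An object of class `scene_config` (a validated list).
#' @examples
#' sc <- scene_config(n_grazers = 2, duration_s = 60)
#' sc$n_frames
#' @export
scene_config <- function(flume_length_cm = 62, flume_width_cm = 8,
                         tile_side_cm = 2.3, tile_rows = 3, tile_cols = 10,
                         removed_tiles = integer(0),
                         px_per_cm = 10, frame_interval_s = 15,
                         duration_s = 7200, n_grazers = 8,
                         marker_rgb = c(255, 105, 180),
                         marker_radius_cm = 0.2, mouth_radius_cm = 0.25,
                         biofilm_rgb = c(60, 90, 40),
                         bare_rgb = c(235, 235, 225),
                         tray_rgb = c(120, 120, 120),
                         seed = NULL) {
  if (!is.numeric(px_per_cm) || length(px_per_cm) != 1L || px_per_cm <= 0) {
    stop("px_per_cm must be a positive scalar")
  }
  if (frame_interval_s <= 0) stop("frame_interval_s must be > 0")
  if (duration_s < 0) stop("duration_s must be >= 0")
  if (n_grazers < 0) stop("n_grazers must be >= 0")
  if (flume_length_cm <= 0 || flume_width_cm <= 0 || tile_side_cm <= 0) {
    stop("flume and tile dimensions must be positive")
  }
  if (tile_cols * tile_side_cm > flume_length_cm + 1e-9 ||
      tile_rows * tile_side_cm > flume_width_cm + 1e-9) {
    stop("tile grid does not fit inside the flume footprint")
  }
  for (col in list(marker_rgb, biofilm_rgb, bare_rgb, tray_rgb)) {
    if (!is_rgb_triple(col)) stop("colours must be RGB triples in [0, 255]")
  }
  if (all(marker_rgb == biofilm_rgb) || all(marker_rgb == bare_rgb)) {
    stop("marker_rgb must differ from biofilm_rgb and bare_rgb")
  }
  n_tiles <- tile_rows * tile_cols
  removed_tiles <- as.integer(removed_tiles)
  if (length(removed_tiles) &&
      (any(removed_tiles < 1L) || any(removed_tiles > n_tiles))) {
    stop("removed_tiles indices must lie in 1..", n_tiles)
  }
  out <- list(
    flume_length_cm = flume_length_cm, flume_width_cm = flume_width_cm,
    tile_side_cm = tile_side_cm, tile_rows = tile_rows,
    tile_cols = tile_cols, removed_tiles = sort(unique(removed_tiles)),
    px_per_cm = px_per_cm, frame_interval_s = frame_interval_s,
    duration_s = duration_s,
    n_frames = as.integer(floor(duration_s / frame_interval_s)) + 1L,
    n_grazers = as.integer(n_grazers),
    marker_rgb = as.numeric(marker_rgb),
    marker_radius_cm = marker_radius_cm,
    mouth_radius_cm = mouth_radius_cm,
    biofilm_rgb = as.numeric(biofilm_rgb),
    bare_rgb = as.numeric(bare_rgb), tray_rgb = as.numeric(tray_rgb),
    seed = seed
  )
  class(out) <- "scene_config"
  out
}

#' @export
print.scene_config <- function(x, ...) {
  cat(sprintf(
    "<scene_config> %g x %g cm flume, %d tiles (%g cm), %d grazers\n",
    x$flume_length_cm, x$flume_width_cm,
    x$tile_rows * x$tile_cols - length(x$removed_tiles), x$tile_side_cm,
    x$n_grazers))
  cat(sprintf("  %d frames every %g s at %g px/cm\n",
              x$n_frames, x$frame_interval_s, x$px_per_cm))
  invisible(x)
}

# Frame dimensions in pixels (rows = width/y, cols = length/x).
scene_frame_dim <- function(scene) {
  c(rows = as.integer(round(scene$flume_width_cm * scene$px_per_cm)),
    cols = as.integer(round(scene$flume_length_cm * scene$px_per_cm)))
}

#' Substrate tile mask for a scene
#'
#' Logical raster (frame-sized) that is `TRUE` on pixels belonging to a
#' tile still present in the tray. The tile grid is centred in the flume
#' footprint; tiles listed in `removed_tiles` are cut out.
#'
#' @param scene a [scene_config()].
#' @return Logical matrix of frame dimensions.
#' @export
tile_mask <- function(scene) {
  dims <- scene_frame_dim(scene)
  s <- scene$px_per_cm
  # pixel-centre coordinates in cm (0-based pixel p has centre (p + 0.5)/s)
  xc <- (seq_len(dims["cols"]) - 0.5) / s
  yc <- (seq_len(dims["rows"]) - 0.5) / s
  grid_w <- scene$tile_cols * scene$tile_side_cm
  grid_h <- scene$tile_rows * scene$tile_side_cm
  x0 <- (scene$flume_length_cm - grid_w) / 2
  y0 <- (scene$flume_width_cm - grid_h) / 2
  col_idx <- floor((xc - x0) / scene$tile_side_cm)  # tile column, 0-based
  row_idx <- floor((yc - y0) / scene$tile_side_cm)
  in_x <- xc >= x0 & xc < x0 + grid_w
  in_y <- yc >= y0 & yc < y0 + grid_h
  mask <- outer(in_y, in_x, `&`)
  if (length(scene$removed_tiles)) {
    tile_no <- outer(row_idx, col_idx, function(r, k) r * scene$tile_cols + k + 1L)
    mask[mask & tile_no %in% scene$removed_tiles] <- FALSE
  }
  mask
}

#' Behavioural movement model for simulated grazers
#'
#' A three-state Markov chain (resting, slow, fast) switching once per
#' frame interval, with a uniform speed sampler per state and a wrapped
#' Gaussian turning kernel (correlated random walk). The speed supports
#' must sit inside the classifier's category bands -- resting \[0, 0.4),
#' slow \[0.4, 4\], fast (4, Inf) cm/h -- so that latent states are
#' recoverable from observed displacements.
#'
#' @param transition_matrix 3 x 3 row-stochastic matrix, states ordered
#'   resting, slow, fast; entry (i, j) is P(next = j | current = i) per
#'   frame interval.
#' @param speed_ranges named list of length-2 numeric ranges (cm/h) for
#'   `resting`, `slow` and `fast`.
#' @param turning_kappa concentration of the turning-angle kernel;
#'   headings evolve by Gaussian increments with SD `1/sqrt(turning_kappa)`
#'   radians. Larger values give straighter paths.
#' @return An object of class `behaviour_model`.
#' @examples
#' bm <- behaviour_model()
#' rowSums(bm$transition_matrix)
#' @export
behaviour_model <- function(transition_matrix = default_transition_matrix(),
                            speed_ranges = list(resting = c(0, 0.3),
                                                slow = c(0.6, 3.5),
                                                fast = c(4.8, 12)),
                            turning_kappa = 2) {
  transition_matrix <- as.matrix(transition_matrix)
  if (!all(dim(transition_matrix) == c(3L, 3L))) {
    stop("transition_matrix must be 3 x 3")
  }
  if (any(transition_matrix < 0) ||
      any(abs(rowSums(transition_matrix) - 1) > 1e-12)) {
    stop("transition_matrix must be row-stochastic (rows sum to 1)")
  }
  need <- c("resting", "slow", "fast")
  if (!all(need %in% names(speed_ranges))) {
    stop("speed_ranges needs entries resting, slow, fast")
  }
  speed_ranges <- speed_ranges[need]
  for (st in need) {
    r <- speed_ranges[[st]]
    if (length(r) != 2L || r[1] > r[2] || r[1] < 0) {
      stop("speed range for ", st, " must be an ordered non-negative pair")
    }
  }
  band <- list(resting = c(0, 0.4), slow = c(0.4, 4), fast = c(4, Inf))
  if (speed_ranges$resting[2] >= band$resting[2]) {
    stop("resting speeds must stay below 0.4 cm/h")
  }
  if (speed_ranges$slow[1] < band$slow[1] || speed_ranges$slow[2] > band$slow[2]) {
    stop("slow speeds must lie within [0.4, 4] cm/h")
  }
  if (speed_ranges$fast[1] <= band$fast[1]) {
    stop("fast speeds must exceed 4 cm/h")
  }
  if (turning_kappa <= 0) stop("turning_kappa must be > 0")
  dimnames(transition_matrix) <- list(need, need)
  structure(list(states = need, transition_matrix = transition_matrix,
                 speed_ranges = speed_ranges, turning_kappa = turning_kappa),
            class = "behaviour_model")
}

#' @rdname behaviour_model
#' @export
default_transition_matrix <- function() {
  matrix(c(0.85, 0.10, 0.05,
           0.15, 0.70, 0.15,
           0.10, 0.20, 0.70),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("resting", "slow", "fast"),
                         c("resting", "slow", "fast")))
}

# Stationary distribution of a row-stochastic matrix; NULL when the unit
# eigenvalue is not simple (e.g. identity matrix).
stationary_distribution <- function(P) {
  ev <- eigen(t(P))
  unit <- which(abs(ev$values - 1) < 1e-9)
  if (length(unit) != 1L) return(NULL)
  v <- Re(ev$vectors[, unit])
  v <- v / sum(v)
  if (any(v < -1e-12)) return(NULL)
  pmax(v, 0) / sum(pmax(v, 0))
}
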