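#' Render time-lapse frames with progressive biofilm depletion
#'
#' Produces the synthetic camera view of a simulated flume: tiles start
#' covered in biofilm, every pixel whose centre comes within
#' `mouth_radius_cm` of a visited grazer position is permanently switched
#' to the bare-tile colour, and each grazer is drawn as an anti-aliased
#' disc of the marker colour on top. The returned cumulative grazed masks
#' are exactly the sets of pixels rendered bare, so area estimators can be
#' scored against them without a separate ground truth.
#'
#' Frames use image conventions: origin at the top-left, x rightward
#' (columns), y downward (rows), 0-based pixel coordinates; the pixel with
#' 0-based coordinates (px, py) has its centre at
#' ((px + 0.5)/px_per_cm, (py + 0.5)/px_per_cm) in flume cm.
#'
#' @param truth a [simulate_trajectories()] result.
#' @param scene the scene; defaults to the one stored in `truth`.
#' @param dir optional directory; when given, frames are written as
#'   zero-padded `frame_000000.png` files and not kept in memory.
#' @param keep_frames keep rendered frames in the return value (default:
#'   only when not writing to `dir`).
#' @param draw_markers draw the grazer marker discs (disable to render
#'   marker-free reference imagery).
#'
#' @return A list of class `flume_render`: `frames` (list of H x W x 3
#'   numeric arrays, 0-255, or NULL), `masks` (list of logical grazed
#'   masks, cumulative), `grazed_px` (integer per frame), `paths` (written
#'   files or NULL), `tile_mask`, `times_s`, and the scene.
#' @export
render_frames <- function(truth, scene = truth$scene, dir = NULL,
                          keep_frames = is.null(dir), draw_markers = TRUE) {
  stopifnot(inherits(truth, "flume_truth"), inherits(scene, "scene_config"))
  if (colour_distance(scene$marker_rgb, scene$biofilm_rgb) <= 60 ||
      colour_distance(scene$marker_rgb, scene$bare_rgb) <= 60) {
    warning("marker colour lies within the default detection tolerance ",
            "of a background colour; detections may be unreliable")
  }
  dims <- scene_frame_dim(scene)
  H <- dims[["rows"]]; Wd <- dims[["cols"]]
  s <- scene$px_per_cm
  tiles <- tile_mask(scene)
  base <- array(rep(scene$tray_rgb, each = H * Wd), dim = c(H, Wd, 3L))
  for (ch in 1:3) {
    plane <- base[, , ch]
    plane[tiles] <- scene$biofilm_rgb[ch]
    base[, , ch] <- plane
  }
  nf <- scene$n_frames
  tr <- truth$trajectories
  pos_x <- matrix(NA_real_, nf, scene$n_grazers)
  pos_y <- matrix(NA_real_, nf, scene$n_grazers)
  if (scene$n_grazers > 0L && nrow(tr)) {
    pos_x[cbind(tr$frame + 1L, tr$grazer_id + 1L)] <- tr$x_cm
    pos_y[cbind(tr$frame + 1L, tr$grazer_id + 1L)] <- tr$y_cm
  }
  grazed <- matrix(FALSE, H, Wd)
  masks <- vector("list", nf)
  frames <- if (keep_frames) vector("list", nf) else NULL
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- file.path(dir, sprintf("frame_%06d.png", 0:(nf - 1L)))
  }
  grazed_px <- integer(nf)
  mouth_r <- scene$mouth_radius_cm
  mark_r_px <- scene$marker_radius_cm * s

  for (f in seq_len(nf)) {
    if (scene$n_grazers > 0L) {
      for (g in seq_len(scene$n_grazers)) {
        grazed <- mark_disc(grazed, tiles, pos_x[f, g], pos_y[f, g],
                            mouth_r, s)
      }
    }
    masks[[f]] <- grazed
    grazed_px[f] <- sum(grazed)
    img <- base
    if (any(grazed)) {
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[grazed] <- scene$bare_rgb[ch]
        img[, , ch] <- plane
      }
    }
    if (draw_markers && scene$n_grazers > 0L) {
      for (g in seq_len(scene$n_grazers)) {
        img <- draw_marker(img, pos_x[f, g], pos_y[f, g], mark_r_px, s,
                           scene$marker_rgb)
      }
    }
    if (keep_frames) frames[[f]] <- img
    if (!is.null(paths)) png::writePNG(img / 255, paths[f])
  }
  structure(list(frames = frames, masks = masks, grazed_px = grazed_px,
                 paths = paths, tile_mask = tiles,
                 times_s = (0:(nf - 1L)) * scene$frame_interval_s,
                 scene = scene),
            class = "flume_render")
}

#' @export
print.flume_render <- function(x, ...) {
  cat(sprintf("<flume_render> %d frames, final grazed %d px\n",
              length(x$masks), x$grazed_px[length(x$grazed_px)]))
  invisible(x)
}

colour_distance <- function(a, b) sqrt(sum((a - b)^2))

# Mark tile pixels whose centres fall within radius_cm of (x_cm, y_cm).
mark_disc <- function(grazed, tiles, x_cm, y_cm, radius_cm, px_per_cm) {
  if (is.na(x_cm) || is.na(y_cm)) return(grazed)
  H <- nrow(grazed); Wd <- ncol(grazed)
  r_px <- radius_cm * px_per_cm
  cx <- x_cm * px_per_cm + 0.5  # 1-based pixel-centre coordinates
  cy <- y_cm * px_per_cm + 0.5
  j0 <- max(1L, floor(cx - r_px)); j1 <- min(Wd, ceiling(cx + r_px))
  i0 <- max(1L, floor(cy - r_px)); i1 <- min(H, ceiling(cy + r_px))
  if (j0 > j1 || i0 > i1) return(grazed)
  jj <- j0:j1; ii <- i0:i1
  d2 <- outer((ii - cy)^2, (jj - cx)^2, `+`)
  hit <- d2 <= r_px^2 & tiles[ii, jj, drop = FALSE]
  grazed[ii, jj] <- grazed[ii, jj, drop = FALSE] | hit
  grazed
}

# Alpha-blend an anti-aliased disc of colour `rgb` into `img`.
draw_marker <- function(img, x_cm, y_cm, r_px, px_per_cm, rgb) {
  if (is.na(x_cm) || is.na(y_cm)) return(img)
  H <- dim(img)[1]; Wd <- dim(img)[2]
  cx <- x_cm * px_per_cm + 0.5
  cy <- y_cm * px_per_cm + 0.5
  pad <- r_px + 1.5
  j0 <- max(1L, floor(cx - pad)); j1 <- min(Wd, ceiling(cx + pad))
  i0 <- max(1L, floor(cy - pad)); i1 <- min(H, ceiling(cy + pad))
  if (j0 > j1 || i0 > i1) return(img)
  jj <- j0:j1; ii <- i0:i1
  d <- sqrt(outer((ii - cy)^2, (jj - cx)^2, `+`))
  cov <- pmin(pmax(r_px + 0.5 - d, 0), 1)  # coverage ramp over one pixel
  if (all(cov == 0)) return(img)
  for (ch in 1:3) {
    patch <- img[ii, jj, ch, drop = TRUE]
    img[ii, jj, ch] <- patch * (1 - cov) + rgb[ch] * cov
  }
  img
}

#' Read a frame image into a 0-255 RGB array
#'
#' Thin wrapper over [png::readPNG()] that rescales to the 0-255 range
#' used throughout the package and drops an alpha channel if present.
#'
#' @param path PNG file path.
#' @return H x W x 3 numeric array in 0-255.
#' @export
read_frame <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) {
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  }
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  img * 255
}
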