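#' Pixel-scale calibration from known tile dimensions
#'
#' @param tile_side_px measured side of a tile in pixels.
#' @param tile_side_cm physical tile side (default 2.3 cm).
#' @return px_per_cm.
#' @examples
#' calibrate_scale(46, 2.3)  # 20 px/cm
#' @export
calibrate_scale <- function(tile_side_px, tile_side_cm = 2.3) {
  if (!is.numeric(tile_side_px) || tile_side_px <= 0 ||
      !is.numeric(tile_side_cm) || tile_side_cm <= 0) {
    stop("tile dimensions must be positive")
  }
  tile_side_px / tile_side_cm
}

#' Total substrate area of a tile tray
#'
#' @param n_tiles number of tiles (>= 0).
#' @param tile_side_cm tile side (cm).
#' @return area in cm2; 30 tiles of 2.3 cm give 158.7 cm2.
#' @export
tile_total_area <- function(n_tiles, tile_side_cm = 2.3) {
  if (n_tiles < 0) stop("n_tiles must be >= 0")
  n_tiles * tile_side_cm^2
}

#' Calibration object for area quantification
#'
#' @param px_per_cm pixel scale (> 0).
#' @param tile_mask logical raster of substrate pixels.
#' @param tile_side_cm tile side (cm), metadata only.
#' @return list of class `area_calibration` with the derived
#'   `total_substrate_cm2 = sum(tile_mask) / px_per_cm^2`.
#' @export
area_calibration <- function(px_per_cm, tile_mask, tile_side_cm = 2.3) {
  if (px_per_cm <= 0) stop("px_per_cm must be > 0")
  stopifnot(is.logical(tile_mask), is.matrix(tile_mask))
  structure(list(px_per_cm = px_per_cm, tile_mask = tile_mask,
                 tile_side_cm = tile_side_cm,
                 total_substrate_cm2 = sum(tile_mask) / px_per_cm^2),
            class = "area_calibration")
}

# Otsu threshold on a numeric vector (256-bin histogram).
otsu_threshold <- function(x) {
  r <- range(x)
  if (diff(r) < .Machine$double.eps) return(r[1])
  h <- graphics::hist(x, breaks = seq(r[1], r[2], length.out = 257L),
                      plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  best <- -Inf; thr <- mids[1]
  w0 <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[length(mu)]
  for (k in seq_len(255L)) {
    if (w0[k] <= 0 || w0[k] >= 1) next
    between <- (mu_t * w0[k] - mu[k])^2 / (w0[k] * (1 - w0[k]))
    if (between > best) {
      best <- between
      thr <- (mids[k] + mids[k + 1L]) / 2
    }
  }
  thr
}

#' Segment grazed (bare) substrate in a frame
#'
#' Marks substrate pixels whose luminance exceeds the biofilm baseline by
#' more than a threshold as grazed -- bare white ceramic is brighter than
#' intact biofilm, so biofilm loss shows up as a positive luminance
#' difference. Pixels in `exclude_mask` (typically a dilated
#' marker-colour match, so grazer bodies are not mistaken for bare tile)
#' are removed before thresholding and never counted. Components smaller
#' than `min_component_px` are removed (area opening).
#'
#' @param frame H x W x 3 RGB array (0-255).
#' @param baseline either a reference RGB frame of the intact biofilm or
#'   a single baseline luminance value.
#' @param calib an [area_calibration()] whose `tile_mask` matches the
#'   frame dimensions.
#' @param threshold luminance-difference threshold; `NULL` (default)
#'   picks it by Otsu's method on the in-mask difference values, floored
#'   at `min_diff`.
#' @param min_diff smallest luminance difference ever treated as biofilm
#'   loss (guards the Otsu fallback against all-intact frames).
#' @param exclude_mask optional logical mask of pixels to ignore.
#' @param min_component_px area-opening size (8-connectivity).
#' @param fill_excluded infer the state of excluded (occluded) pixels
#'   from their surroundings: an excluded region is counted as grazed
#'   when the majority of its non-excluded border pixels are grazed.
#'   Grazers occlude the substrate they sit on -- usually substrate they
#'   have just grazed -- so leaving this off biases areas low.
#' @return Logical grazed mask (H x W).
#' @export
segment_grazed <- function(frame, baseline, calib, threshold = NULL,
                           min_diff = 10, exclude_mask = NULL,
                           min_component_px = 5L, fill_excluded = TRUE) {
  stopifnot(inherits(calib, "area_calibration"))
  d <- dim(frame)
  if (length(d) != 3L || d[3] != 3L) stop("frame must be H x W x 3")
  if (!all(d[1:2] == dim(calib$tile_mask))) {
    stop("frame and tile_mask dimensions differ")
  }
  lum <- luminance(frame)
  base_lum <- if (is.array(baseline) && length(dim(baseline)) == 3L) {
    if (!all(dim(baseline)[1:2] == d[1:2])) {
      stop("baseline and frame dimensions differ")
    }
    luminance(baseline)
  } else if (is.numeric(baseline) && length(baseline) == 1L) {
    matrix(baseline, d[1], d[2])
  } else {
    stop("baseline must be an RGB raster or a scalar luminance")
  }
  diff_lum <- lum - base_lum
  consider <- calib$tile_mask
  if (!is.null(exclude_mask)) {
    stopifnot(all(dim(exclude_mask) == d[1:2]))
    consider <- consider & !exclude_mask
  }
  if (is.null(threshold)) {
    vals <- diff_lum[consider]
    # Otsu needs a bimodal field; a (near-)constant difference image --
    # fully intact or fully bare -- falls back on the absolute floor
    threshold <- if (length(vals) && diff(range(vals)) > min_diff) {
      max(otsu_threshold(vals), min_diff)
    } else {
      min_diff
    }
  }
  grazed <- consider & diff_lum > threshold
  if (min_component_px > 1L && any(grazed)) {
    lab <- label_components(grazed)
    sizes <- tabulate(lab[lab > 0L])
    small <- which(sizes < min_component_px)
    if (length(small)) grazed[lab %in% small] <- FALSE
  }
  if (fill_excluded && !is.null(exclude_mask)) {
    occ <- exclude_mask & calib$tile_mask
    if (any(occ)) {
      lab <- label_components(occ)
      for (k in seq_len(max(lab))) {
        region <- lab == k
        border <- dilate_mask(region, 1L) & !occ & calib$tile_mask
        if (any(border) && mean(grazed[border]) > 0.5) {
          grazed[region] <- TRUE
        }
      }
    }
  }
  grazed
}

#' Dilate a logical mask
#'
#' Square structuring element of half-width `radius_px`; used to grow the
#' marker-colour match before excluding it from grazed-area segmentation
#' (anti-aliased marker rims would otherwise leak into the bare class).
#'
#' @param mask logical matrix.
#' @param radius_px dilation radius in pixels.
#' @return Logical matrix.
#' @export
dilate_mask <- function(mask, radius_px = 1L) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (radius_px < 1L || !any(mask)) return(mask)
  H <- nrow(mask); W <- ncol(mask)
  out <- mask
  for (di in -radius_px:radius_px) for (dj in -radius_px:radius_px) {
    if (di == 0L && dj == 0L) next
    si <- max(1L, 1L + di):min(H, H + di)
    ti <- max(1L, 1L - di):min(H, H - di)
    sj <- max(1L, 1L + dj):min(W, W + dj)
    tj <- max(1L, 1L - dj):min(W, W - dj)
    out[ti, tj] <- out[ti, tj] | mask[si, sj]
  }
  out
}

#' Grazed-area time series
#'
#' Converts a sequence of grazed masks (one per analysed frame, e.g.
#' every 12 h) into calibrated area samples.
#'
#' @param masks list of logical grazed masks.
#' @param calib an [area_calibration()].
#' @param times_h numeric vector of sample times (h), same length.
#' @param cumulative accumulate masks over time (union with all earlier
#'   masks) before measuring. Grazing is irreversible, so a pixel once
#'   seen bare stays grazed even if a grazer later occludes it; this
#'   also makes the estimated series monotone by construction.
#' @return data.frame with `time_h`, `grazed_px`, `grazed_cm2`,
#'   `fraction_percent` (of the calibrated substrate area).
#' @export
area_series <- function(masks, calib, times_h = seq_along(masks) - 1,
                        cumulative = FALSE) {
  stopifnot(inherits(calib, "area_calibration"),
            length(masks) == length(times_h))
  if (cumulative && length(masks) > 1L) {
    for (k in seq.int(2L, length(masks))) {
      masks[[k]] <- masks[[k]] | masks[[k - 1L]]
    }
  }
  px <- vapply(masks, sum, numeric(1))
  cm2 <- px / calib$px_per_cm^2
  data.frame(time_h = times_h, grazed_px = as.integer(px),
             grazed_cm2 = cm2,
             fraction_percent = grazed_fraction(cm2, calib$total_substrate_cm2))
}

#' Grazed fraction of the substrate
#'
#' @param grazed_cm2 grazed area (cm2), vectorised.
#' @param total_cm2 total substrate area (cm2, > 0).
#' @return percentage `100 * grazed / total`; warns when grazed exceeds
#'   total beyond rounding tolerance.
#' @examples
#' round(grazed_fraction(151, 158.7))  # 95
#' round(grazed_fraction(41, 158.7))   # 26
#' @export
grazed_fraction <- function(grazed_cm2, total_cm2) {
  if (total_cm2 <= 0) stop("total_cm2 must be > 0")
  if (any(grazed_cm2 < 0)) stop("grazed_cm2 must be >= 0")
  if (any(grazed_cm2 > total_cm2 * (1 + 1e-9))) {
    warning("grazed area exceeds the substrate total")
  }
  100 * grazed_cm2 / total_cm2
}
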