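#' Colour specification for marker matching
#'
#' Defines which pixels count as "marker-coloured": either all pixels
#' within a Euclidean distance of the target colour in the 0-255 RGB cube
#' (default, tolerance 60), or all pixels within a per-channel absolute
#' deviation.
#'
#' @param target_rgb length-3 target colour, 0-255.
#' @param tolerance maximum deviation (Euclidean RGB distance or
#'   per-channel absolute difference, depending on `mode`).
#' @param mode `"euclidean"` or `"per_channel"`.
#' @return An object of class `colour_spec`.
#' @export
colour_spec <- function(target_rgb, tolerance = 60,
                        mode = c("euclidean", "per_channel")) {
  mode <- match.arg(mode)
  if (!is_rgb_triple(target_rgb)) stop("target_rgb must be an RGB triple in [0, 255]")
  if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance < 0) {
    stop("tolerance must be a non-negative scalar")
  }
  structure(list(target_rgb = as.numeric(target_rgb),
                 tolerance = tolerance, mode = mode),
            class = "colour_spec")
}

#' Match marker-coloured pixels in a frame
#'
#' @param frame H x W x 3 numeric RGB array (0-255).
#' @param spec a [colour_spec()].
#' @return Logical H x W mask, `TRUE` where the pixel satisfies the
#'   colour criterion.
#' @examples
#' f <- array(0, dim = c(4, 4, 3))
#' f[2, 2, ] <- c(255, 105, 180)
#' sum(match_colour(f, colour_spec(c(255, 105, 180), tolerance = 0)))
#' @export
match_colour <- function(frame, spec) {
  stopifnot(inherits(spec, "colour_spec"))
  d <- dim(frame)
  if (length(d) != 3L || d[3] != 3L) {
    stop("frame must be an H x W x 3 RGB raster")
  }
  if (d[1] == 0L || d[2] == 0L) stop("frame must be non-empty")
  dr <- frame[, , 1] - spec$target_rgb[1]
  dg <- frame[, , 2] - spec$target_rgb[2]
  db <- frame[, , 3] - spec$target_rgb[3]
  if (spec$mode == "euclidean") {
    dr * dr + dg * dg + db * db <= spec$tolerance^2
  } else {
    abs(dr) <= spec$tolerance & abs(dg) <= spec$tolerance &
      abs(db) <= spec$tolerance
  }
}

#' Label connected components (8-connectivity)
#'
#' Two-dimensional connected-component labelling with 8-connectivity
#' (diagonal neighbours connect), implemented by iterative minimum-label
#' propagation. Anti-aliased disc edges therefore remain part of a single
#' component.
#'
#' @param mask logical matrix.
#' @return Integer matrix of the same shape: 0 for background, components
#'   numbered from 1 in first-pixel (column-major) order.
#' @export
label_components <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(Inf, H, W)
  lab[mask] <- which(mask)
  if (!any(mask)) return(matrix(0L, H, W))
  pad <- function(m) {
    out <- matrix(Inf, H + 2L, W + 2L)
    out[2:(H + 1L), 2:(W + 1L)] <- m
    out
  }
  repeat {
    p <- pad(lab)
    cand <- lab
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0L && dj == 0L) next
      cand <- pmin(cand, p[(2:(H + 1L)) + di, (2:(W + 1L)) + dj])
    }
    cand[!mask] <- Inf
    if (identical(cand, lab)) break
    lab <- cand
  }
  out <- matrix(0L, H, W)
  ids <- sort(unique(lab[mask]))
  out[mask] <- match(lab[mask], ids)
  out
}

#' Extract marker blobs as sub-pixel detections
#'
#' Connected components of a colour-match mask become detections; each
#' carries the arithmetic mean of its member pixels' 0-based (x, y)
#' coordinates (sub-pixel centroid) and its pixel count. Components
#' outside `[min_blob_px, max_blob_px]` are dropped. Detections are
#' sorted by pixel count descending, then x, then y.
#'
#' @param mask logical matrix, typically from [match_colour()].
#' @param min_blob_px,max_blob_px inclusive size filter in pixels.
#' @param frame_index 0-based frame index recorded on each detection.
#' @return data.frame with `frame`, `x_px`, `y_px`, `pixel_count`.
#' @examples
#' m <- matrix(FALSE, 30, 30); m[21:23, 11:13] <- TRUE
#' extract_blobs(m)  # centroid (11, 21) for a block with corner (10, 20)
#' @export
extract_blobs <- function(mask, min_blob_px = 1L, max_blob_px = Inf,
                          frame_index = 0L) {
  stopifnot(min_blob_px >= 1L, max_blob_px >= min_blob_px)
  empty <- data.frame(frame = integer(0), x_px = numeric(0),
                      y_px = numeric(0), pixel_count = integer(0))
  if (!any(mask)) return(empty)
  lab <- label_components(mask)
  idx <- which(lab > 0L)
  comp <- lab[idx]
  rows <- (idx - 1L) %% nrow(mask)        # 0-based y
  cols <- (idx - 1L) %/% nrow(mask)       # 0-based x
  count <- tabulate(comp)
  keep <- which(count >= min_blob_px & count <= max_blob_px)
  if (!length(keep)) return(empty)
  cx <- tapply(cols, comp, mean)[as.character(keep)]
  cy <- tapply(rows, comp, mean)[as.character(keep)]
  out <- data.frame(frame = as.integer(frame_index),
                    x_px = as.numeric(cx), y_px = as.numeric(cy),
                    pixel_count = count[keep])
  out <- out[order(-out$pixel_count, out$x_px, out$y_px), ]
  rownames(out) <- NULL
  out
}

#' Detect markers across a frame sequence
#'
#' Runs [match_colour()] and [extract_blobs()] over a list of frames (or
#' PNG paths) and binds the per-frame detections.
#'
#' @param frames list of RGB arrays, or character vector of PNG paths.
#' @param spec a [colour_spec()].
#' @param min_blob_px,max_blob_px blob size filter; the defaults accept
#'   blobs between 25% and 400% of `expected_area_px` when that is given.
#' @param expected_area_px expected marker disc area in pixels (e.g.
#'   `pi * (marker_radius_cm * px_per_cm)^2`); used only to derive the
#'   default size filter.
#' @return data.frame of detections (`frame`, `x_px`, `y_px`,
#'   `pixel_count`), frames numbered 0-based in input order.
#' @export
detect_sequence <- function(frames, spec, expected_area_px = NULL,
                            min_blob_px = NULL, max_blob_px = NULL) {
  if (!is.null(expected_area_px)) {
    if (is.null(min_blob_px)) min_blob_px <- max(1L, floor(0.25 * expected_area_px))
    if (is.null(max_blob_px)) max_blob_px <- ceiling(4 * expected_area_px)
  }
  if (is.null(min_blob_px)) min_blob_px <- 1L
  if (is.null(max_blob_px)) max_blob_px <- Inf
  out <- vector("list", length(frames))
  for (f in seq_along(frames)) {
    frame <- if (is.character(frames)) read_frame(frames[f]) else frames[[f]]
    out[[f]] <- extract_blobs(match_colour(frame, spec),
                              min_blob_px = min_blob_px,
                              max_blob_px = max_blob_px,
                              frame_index = f - 1L)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
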