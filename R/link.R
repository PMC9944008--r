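#' Linking parameters
#'
#' @param n_expected number of grazers expected in the flume (tracks are
#'   never created beyond this).
#' @param max_step_px assignment gate: a detection can extend a track only
#'   if it lies within `max_step_px * (gap_length + 1)` of the track's
#'   last known position. A sensible default is ~3x the 99th-percentile
#'   per-interval displacement of a fast mover.
#' @param max_gap_frames gap length beyond which the gate stops growing.
#' @return An object of class `link_params`.
#' @export
link_params <- function(n_expected = 8L, max_step_px = 20,
                        max_gap_frames = 10L) {
  if (n_expected < 1L) stop("n_expected must be >= 1")
  if (max_step_px <= 0) stop("max_step_px must be > 0")
  if (max_gap_frames < 0L) stop("max_gap_frames must be >= 0")
  structure(list(n_expected = as.integer(n_expected),
                 max_step_px = max_step_px,
                 max_gap_frames = as.integer(max_gap_frames)),
            class = "link_params")
}

# Jonker-Volgenant style shortest-augmenting-path solver for the square
# linear assignment problem. Finite costs only. Returns, for each row,
# the assigned column.
lap_solve <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n, all(is.finite(cost)))
  if (n == 0L) return(integer(0))
  u <- numeric(n)          # row potentials
  v <- numeric(n + 1L)     # column potentials, index 1 = virtual column
  p <- integer(n + 1L)     # p[j]: row currently assigned to column j
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq.int(2L, n + 1L)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1L] - u[i0] - v[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) {
          if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  ans <- integer(n)
  for (j in seq.int(2L, n + 1L)) ans[p[j]] <- j - 1L
  ans
}

# Large-but-finite cost standing in for a forbidden pairing.
.FORBIDDEN <- 1e8

#' Assign detections to tracks in one frame
#'
#' Globally optimal one-to-one assignment between track positions and
#' detections minimising total Euclidean distance, subject to a gating
#' distance per track: among assignments the number of within-gate
#' matches is maximised first, then total distance is minimised (this
#' coincides with the pairwise nearest-neighbour rule for well-separated
#' slow movers, and is well defined under ties). Unmatched tracks record
#' a gap; surplus detections are reported unmatched.
#'
#' @param track_positions data.frame with `track_id`, `x_px`, `y_px`
#'   (last known position per active track).
#' @param detections data.frame with `x_px`, `y_px` for the frame.
#' @param params a [link_params()].
#' @param gate_px optional per-track gate overriding `params$max_step_px`
#'   (recycled to the number of tracks).
#' @return list with `matches` (data.frame `track_id`, `detection`
#'   1-based row index into `detections`, `cost`), `unmatched_tracks`
#'   (track ids) and `unmatched_detections` (row indices).
#' @export
assign_frame <- function(track_positions, detections, params,
                         gate_px = NULL) {
  stopifnot(inherits(params, "link_params"))
  nt <- nrow(track_positions)
  nd <- if (is.null(detections)) 0L else nrow(detections)
  if (nt > params$n_expected) stop("more tracks than n_expected")
  empty <- list(matches = data.frame(track_id = integer(0),
                                     detection = integer(0),
                                     cost = numeric(0)),
                unmatched_tracks = integer(0),
                unmatched_detections = integer(0))
  if (nt == 0L && nd == 0L) return(empty)
  if (nt == 0L) {
    empty$unmatched_detections <- seq_len(nd)
    return(empty)
  }
  if (is.null(gate_px)) gate_px <- params$max_step_px
  gate_px <- rep_len(gate_px, nt)
  if (nd == 0L) {
    empty$unmatched_tracks <- track_positions$track_id
    return(empty)
  }
  dx <- outer(track_positions$x_px, detections$x_px, `-`)
  dy <- outer(track_positions$y_px, detections$y_px, `-`)
  cost <- sqrt(dx * dx + dy * dy)
  allowed <- cost <= gate_px
  cost[!allowed] <- .FORBIDDEN
  # square padding: diagonal "stay unmatched" slots priced so that any
  # within-gate match is preferred over leaving both ends unmatched
  D <- max(gate_px) + 1
  N <- nt + nd
  M <- matrix(.FORBIDDEN, N, N)
  M[seq_len(nt), seq_len(nd)] <- cost
  for (i in seq_len(nt)) M[i, nd + i] <- D
  for (j in seq_len(nd)) M[nt + j, j] <- D
  M[seq.int(nt + 1L, N), seq.int(nd + 1L, N)] <- 0
  assign_col <- lap_solve(M)
  matched_t <- integer(0); matched_d <- integer(0); matched_c <- numeric(0)
  for (i in seq_len(nt)) {
    j <- assign_col[i]
    if (j <= nd && allowed[i, j]) {
      matched_t <- c(matched_t, i)
      matched_d <- c(matched_d, j)
      matched_c <- c(matched_c, cost[i, j])
    }
  }
  list(matches = data.frame(track_id = track_positions$track_id[matched_t],
                            detection = matched_d, cost = matched_c),
       unmatched_tracks = setdiff(track_positions$track_id,
                                  track_positions$track_id[matched_t]),
       unmatched_detections = setdiff(seq_len(nd), matched_d))
}

#' Link a detection sequence into grazer tracks
#'
#' Processes frames in temporal order, extending each track with the
#' frame's optimally assigned detection. A track that misses a detection
#' records a gap and keeps its last known position (no extrapolation);
#' the gate grows with the gap length, `max_step_px * (gap + 1)`, so a
#' reappearing detection can close the gap. Tracks are created from the
#' first frame's detections sorted lexicographically by (x, y), ids
#' `0..n-1`; if fewer than `n_expected` appear initially, the remaining
#' tracks start at their first unmatched detection.
#'
#' @param detections data.frame with 0-based `frame`, `x_px`, `y_px`.
#' @param params a [link_params()].
#' @param initial_positions optional `n_expected` x 2 matrix of known
#'   starting positions (px); when given, all tracks exist from frame 0.
#' @param n_frames number of frames spanned (default: `max(frame) + 1`).
#' @return data.frame of class `flume_tracks` with one row per (track,
#'   frame): `track_id`, `frame`, `x_px`, `y_px`, `observed`; coordinates
#'   are `NA` on unobserved frames.
#' @export
link_sequence <- function(detections, params, initial_positions = NULL,
                          n_frames = NULL) {
  stopifnot(inherits(params, "link_params"))
  if (is.null(n_frames)) {
    n_frames <- if (nrow(detections)) max(detections$frame) + 1L else 0L
  }
  n_frames <- as.integer(n_frames)
  ne <- params$n_expected
  # track state
  ids <- integer(0)
  last_x <- numeric(0); last_y <- numeric(0); gap <- integer(0)
  if (!is.null(initial_positions)) {
    initial_positions <- as.matrix(initial_positions)
    stopifnot(nrow(initial_positions) == ne, ncol(initial_positions) == 2L)
    ids <- 0:(ne - 1L)
    last_x <- initial_positions[, 1]
    last_y <- initial_positions[, 2]
    gap <- rep(0L, ne)
  }
  obs <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    dets <- detections[detections$frame == f - 1L, , drop = FALSE]
    if (nrow(dets)) dets <- dets[order(dets$x_px, dets$y_px), , drop = FALSE]
    matched_rows <- NULL
    unmatched_det <- seq_len(nrow(dets))
    if (length(ids)) {
      gates <- params$max_step_px *
        (pmin(gap, params$max_gap_frames) + 1L)
      tp <- data.frame(track_id = ids, x_px = last_x, y_px = last_y)
      asg <- assign_frame(tp, dets, params, gate_px = gates)
      if (nrow(asg$matches)) {
        m <- match(asg$matches$track_id, ids)
        last_x[m] <- dets$x_px[asg$matches$detection]
        last_y[m] <- dets$y_px[asg$matches$detection]
        gap[m] <- 0L
        matched_rows <- data.frame(track_id = asg$matches$track_id,
                                   frame = f - 1L,
                                   x_px = last_x[m], y_px = last_y[m])
      }
      miss <- match(asg$unmatched_tracks, ids)
      gap[miss] <- gap[miss] + 1L
      unmatched_det <- asg$unmatched_detections
    }
    # spawn new tracks from surplus detections, up to n_expected
    if (length(unmatched_det) && length(ids) < ne) {
      take <- unmatched_det[seq_len(min(length(unmatched_det),
                                        ne - length(ids)))]
      new_ids <- seq.int(length(ids), length.out = length(take))
      ids <- c(ids, new_ids)
      last_x <- c(last_x, dets$x_px[take])
      last_y <- c(last_y, dets$y_px[take])
      gap <- c(gap, rep(0L, length(take)))
      matched_rows <- rbind(matched_rows,
                            data.frame(track_id = new_ids, frame = f - 1L,
                                       x_px = dets$x_px[take],
                                       y_px = dets$y_px[take]))
    }
    obs[[f]] <- matched_rows
  }
  observed <- do.call(rbind, obs)
  all_ids <- if (!is.null(initial_positions)) 0:(ne - 1L) else ids
  if (!length(all_ids)) all_ids <- integer(0)
  grid <- expand.grid(frame = seq_len(n_frames) - 1L, track_id = all_ids)
  grid <- grid[, c("track_id", "frame")]
  grid$x_px <- NA_real_
  grid$y_px <- NA_real_
  grid$observed <- FALSE
  if (!is.null(observed) && nrow(observed)) {
    key <- paste(grid$track_id, grid$frame)
    okey <- paste(observed$track_id, observed$frame)
    m <- match(okey, key)
    grid$x_px[m] <- observed$x_px
    grid$y_px[m] <- observed$y_px
    grid$observed[m] <- TRUE
  }
  grid <- grid[order(grid$track_id, grid$frame), ]
  rownames(grid) <- NULL
  attr(grid, "initial_positions") <- initial_positions
  class(grid) <- c("flume_tracks", "data.frame")
  grid
}
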