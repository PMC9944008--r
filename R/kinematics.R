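#' Calibrated speeds from linked tracks
#'
#' One movement record per consecutive pair of *observed* entries of each
#' track: the Euclidean pixel displacement is converted to cm with the
#' pixel scale, elapsed time is `(frame_to - frame_from) *
#' frame_interval_s` (an interval spanning a detection gap uses the total
#' elapsed time), and the speed in cm/h is classified with
#' [classify_speed()].
#'
#' @param tracks data.frame from [link_sequence()] (or any data.frame
#'   with `track_id`, `frame`, `x_px`, `y_px`, `observed`).
#' @param px_per_cm pixel scale (> 0).
#' @param frame_interval_s frame interval in seconds.
#' @param flume_id optional flume label stamped on every record.
#' @return data.frame with `flume_id` (if given), `track_id`,
#'   `frame_from`, `frame_to`, `elapsed_s`, `displacement_cm`,
#'   `speed_cm_per_h`, `category`. Tracks with fewer than two observed
#'   entries contribute nothing.
#' @examples
#' tr <- data.frame(track_id = 0L, frame = 0:1, x_px = c(0, 30),
#'                  y_px = c(0, 40), observed = TRUE)
#' compute_speeds(tr, px_per_cm = 10, frame_interval_s = 15)
#' @export
compute_speeds <- function(tracks, px_per_cm, frame_interval_s,
                           flume_id = NULL) {
  if (!is.numeric(px_per_cm) || px_per_cm <= 0) {
    stop("px_per_cm must be > 0")
  }
  if (frame_interval_s <= 0) stop("frame_interval_s must be > 0")
  obs <- tracks[tracks$observed & !is.na(tracks$x_px), , drop = FALSE]
  pieces <- lapply(split(obs, obs$track_id), function(d) {
    d <- d[order(d$frame), , drop = FALSE]
    if (nrow(d) < 2L) return(NULL)
    k <- nrow(d) - 1L
    disp_px <- sqrt(diff(d$x_px)^2 + diff(d$y_px)^2)
    elapsed <- diff(d$frame) * frame_interval_s
    disp_cm <- disp_px / px_per_cm
    speed <- disp_cm / (elapsed / 3600)
    data.frame(track_id = d$track_id[1],
               frame_from = d$frame[seq_len(k)],
               frame_to = d$frame[seq_len(k) + 1L],
               elapsed_s = elapsed, displacement_cm = disp_cm,
               speed_cm_per_h = speed,
               category = classify_speed(speed),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    out <- data.frame(track_id = integer(0), frame_from = integer(0),
                      frame_to = integer(0), elapsed_s = numeric(0),
                      displacement_cm = numeric(0),
                      speed_cm_per_h = numeric(0),
                      category = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  if (!is.null(flume_id)) out <- cbind(flume_id = flume_id, out)
  out
}

#' Classify a movement speed
#'
#' Partition of the non-negative speed axis into the three behavioural
#' categories: resting `[0, 0.4)`, slow `[0.4, 4]`, fast `(4, Inf)` cm/h.
#' The 0.4 boundary belongs to "slow" (resting is strictly below 0.4) and
#' the 4 boundary to "slow".
#'
#' @param speed_cm_per_h numeric vector of non-negative speeds (cm/h).
#' @return character vector in `{"resting", "slow", "fast"}`.
#' @examples
#' classify_speed(c(0, 0.39, 0.4, 4, 4.0001))
#' @export
classify_speed <- function(speed_cm_per_h) {
  if (any(is.na(speed_cm_per_h)) || any(speed_cm_per_h < 0)) {
    stop("speeds must be non-negative and non-missing")
  }
  ifelse(speed_cm_per_h < 0.4, "resting",
         ifelse(speed_cm_per_h <= 4, "slow", "fast"))
}

#' Tally movement categories per flume
#'
#' Counts resting / slow / fast movement records per flume; the grand
#' total equals the number of classified intervals.
#'
#' @param records data.frame from [compute_speeds()] carrying a
#'   `flume_id` column (and optionally `treatment`).
#' @return data.frame with `flume_id`, `treatment` (if present),
#'   `resting`, `slow`, `fast`, `total`.
#' @export
tally_categories <- function(records) {
  if (!"flume_id" %in% names(records)) {
    stop("records must carry a flume_id column")
  }
  cats <- c("resting", "slow", "fast")
  flumes <- unique(records$flume_id)
  rows <- lapply(flumes, function(fl) {
    d <- records[records$flume_id == fl, , drop = FALSE]
    counts <- vapply(cats, function(cc) sum(d$category == cc), integer(1))
    out <- data.frame(flume_id = fl, resting = counts[["resting"]],
                      slow = counts[["slow"]], fast = counts[["fast"]],
                      total = nrow(d))
    if ("treatment" %in% names(d)) {
      out <- cbind(out[1], treatment = d$treatment[1], out[-1])
    }
    out
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(flume_id = character(0), resting = integer(0),
                      slow = integer(0), fast = integer(0),
                      total = integer(0))
  }
  rownames(out) <- NULL
  out
}
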