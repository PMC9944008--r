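#' Simulate ground-truth grazer trajectories
#'
#' Runs a state-switching correlated random walk for each grazer: at every
#' frame interval the behavioural state evolves by the model's Markov
#' chain, a speed is drawn uniformly from the state's band, the heading
#' turns by a wrapped Gaussian increment, and the grazer advances by
#' exactly `speed * interval`. A step that would leave the flume has the
#' offending velocity component reflected before it is taken, so every
#' realised per-interval displacement equals the sampled step length and
#' the latent state remains recoverable from kinematics alone.
#'
#' @param scene a [scene_config()].
#' @param behaviour a [behaviour_model()].
#' @param seed integer seed; the simulation is fully deterministic given
#'   it. Defaults to `scene$seed`.
#' @param init_state optional state name (`"resting"`, `"slow"`, `"fast"`)
#'   forced on all grazers at frame 0; by default initial states are drawn
#'   from the chain's stationary distribution (uniform when the chain is
#'   reducible and no unique stationary distribution exists).
#' @param init_positions optional `n_grazers` x 2 matrix of starting
#'   positions in cm; by default positions are drawn uniformly inside the
#'   flume with a marker-radius margin.
#'
#' @return An object of class `flume_truth`: a list with `trajectories`
#'   (data.frame `frame` 0-based, `grazer_id` 0-based, `x_cm`, `y_cm`,
#'   `state`), the scene and behaviour objects, and the seed. The state in
#'   row (frame f, grazer g) is the state that generates the step from
#'   frame f to frame f + 1; the final frame repeats the last state.
#' @examples
#' tr <- simulate_trajectories(scene_config(n_grazers = 2, duration_s = 150),
#'                             behaviour_model(), seed = 1)
#' head(tr$trajectories)
#' @export
simulate_trajectories <- function(scene, behaviour, seed = scene$seed,
                                  init_state = NULL, init_positions = NULL) {
  stopifnot(inherits(scene, "scene_config"),
            inherits(behaviour, "behaviour_model"))
  if (is.null(seed)) stop("a seed is required for reproducible simulation")
  n <- scene$n_grazers
  nf <- scene$n_frames
  dt_h <- scene$frame_interval_s / 3600
  L <- scene$flume_length_cm
  W <- scene$flume_width_cm
  margin <- min(scene$marker_radius_cm, L / 4, W / 4)
  P <- behaviour$transition_matrix
  states <- behaviour$states
  turn_sd <- 1 / sqrt(behaviour$turning_kappa)

  if (!is.null(init_state)) {
    init_state <- match.arg(init_state, states)
  }
  if (!is.null(init_positions)) {
    init_positions <- as.matrix(init_positions)
    stopifnot(nrow(init_positions) == n, ncol(init_positions) == 2L)
    if (any(init_positions[, 1] < 0) || any(init_positions[, 1] > L) ||
        any(init_positions[, 2] < 0) || any(init_positions[, 2] > W)) {
      stop("init_positions must lie inside the flume")
    }
  }

  res <- with_seed(seed, {
    pos <- array(NA_real_, dim = c(nf, n, 2L))
    st <- matrix(NA_integer_, nrow = nf, ncol = n)
    if (n > 0L) {
      if (is.null(init_positions)) {
        pos[1, , 1] <- stats::runif(n, margin, L - margin)
        pos[1, , 2] <- stats::runif(n, margin, W - margin)
      } else {
        pos[1, , ] <- init_positions
      }
      if (is.null(init_state)) {
        pi0 <- stationary_distribution(P)
        if (is.null(pi0)) pi0 <- rep(1 / 3, 3)
        st[1, ] <- sample.int(3L, n, replace = TRUE, prob = pi0)
      } else {
        st[1, ] <- match(init_state, states)
      }
      heading <- stats::runif(n, 0, 2 * pi)
      if (nf > 1L) {
        for (f in seq_len(nf - 1L)) {
          cur <- st[f, ]
          rng <- behaviour$speed_ranges
          speed <- numeric(n)
          for (k in 1:3) {
            idx <- which(cur == k)
            if (length(idx)) {
              r <- rng[[k]]
              speed[idx] <- stats::runif(length(idx), r[1], r[2])
            }
          }
          heading <- heading + stats::rnorm(n, 0, turn_sd)
          step <- speed * dt_h
          dx <- step * cos(heading)
          dy <- step * sin(heading)
          x0 <- pos[f, , 1]; y0 <- pos[f, , 2]
          # reflect the heading off a wall before moving, so the step
          # keeps its full length (displacement == speed * dt)
          flip_x <- (x0 + dx < 0) | (x0 + dx > L)
          dx[flip_x] <- -dx[flip_x]
          flip_y <- (y0 + dy < 0) | (y0 + dy > W)
          dy[flip_y] <- -dy[flip_y]
          heading[flip_x | flip_y] <- atan2(dy[flip_x | flip_y],
                                            dx[flip_x | flip_y])
          x1 <- pmin(pmax(x0 + dx, 0), L)  # numerical guard only
          y1 <- pmin(pmax(y0 + dy, 0), W)
          pos[f + 1L, , 1] <- x1
          pos[f + 1L, , 2] <- y1
          # state transition for the next interval
          nxt <- integer(n)
          for (g in seq_len(n)) {
            nxt[g] <- sample.int(3L, 1L, prob = P[cur[g], ])
          }
          st[f + 1L, ] <- nxt
        }
        st[nf, ] <- st[nf - 1L, ]  # last frame has no outgoing interval
      }
    }
    list(pos = pos, st = st)
  })

  traj <- if (n > 0L) {
    data.frame(
      frame = rep(0:(nf - 1L), times = n),
      grazer_id = rep(0:(n - 1L), each = nf),
      x_cm = as.vector(res$pos[, , 1]),
      y_cm = as.vector(res$pos[, , 2]),
      state = states[as.vector(res$st)],
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(frame = integer(0), grazer_id = integer(0),
               x_cm = numeric(0), y_cm = numeric(0),
               state = character(0), stringsAsFactors = FALSE)
  }
  structure(list(trajectories = traj, scene = scene, behaviour = behaviour,
                 seed = seed),
            class = "flume_truth")
}

#' @export
print.flume_truth <- function(x, ...) {
  cat(sprintf("<flume_truth> %d grazers x %d frames (seed %s)\n",
              x$scene$n_grazers, x$scene$n_frames, format(x$seed)))
  invisible(x)
}

#' Ground-truth per-interval movement records
#'
#' Displacement, speed and the generating latent state for every frame
#' interval of a simulated truth object; the reference against which
#' tracking and classification are scored.
#'
#' @param truth a [simulate_trajectories()] result.
#' @return data.frame with `grazer_id`, `frame_from`, `frame_to`,
#'   `displacement_cm`, `speed_cm_per_h`, `state`.
#' @export
truth_intervals <- function(truth) {
  stopifnot(inherits(truth, "flume_truth"))
  tr <- truth$trajectories
  nf <- truth$scene$n_frames
  if (nf < 2L || nrow(tr) == 0L) {
    return(data.frame(grazer_id = integer(0), frame_from = integer(0),
                      frame_to = integer(0), displacement_cm = numeric(0),
                      speed_cm_per_h = numeric(0), state = character(0),
                      stringsAsFactors = FALSE))
  }
  dt_h <- truth$scene$frame_interval_s / 3600
  out <- lapply(split(tr, tr$grazer_id), function(d) {
    d <- d[order(d$frame), ]
    k <- nrow(d) - 1L
    disp <- sqrt(diff(d$x_cm)^2 + diff(d$y_cm)^2)
    data.frame(grazer_id = d$grazer_id[1], frame_from = d$frame[1:k],
               frame_to = d$frame[1:k + 1L], displacement_cm = disp,
               speed_cm_per_h = disp / dt_h, state = d$state[1:k],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
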