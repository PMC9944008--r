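# Independent brute-force oracles used to verify the implementation.

# 8-connected component labelling by breadth-first flood fill.
oracle_label <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (mask[i, j] && lab[i, j] == 0L) {
      nxt <- nxt + 1L
      queue <- list(c(i, j))
      lab[i, j] <- nxt
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (di in -1:1) for (dj in -1:1) {
          ii <- p[1] + di; jj <- p[2] + dj
          if (ii >= 1 && ii <= H && jj >= 1 && jj <= W &&
              mask[ii, jj] && lab[ii, jj] == 0L) {
            lab[ii, jj] <- nxt
            queue[[length(queue) + 1L]] <- c(ii, jj)
          }
        }
      }
    }
  }
  lab
}

# Blob summary (count + centroid in 0-based x/y) from an oracle labelling.
oracle_blobs <- function(mask) {
  lab <- oracle_label(mask)
  ks <- setdiff(sort(unique(as.vector(lab))), 0L)
  do.call(rbind, lapply(ks, function(k) {
    idx <- which(lab == k)
    rows <- (idx - 1L) %% nrow(mask)
    cols <- (idx - 1L) %/% nrow(mask)
    data.frame(x_px = mean(cols), y_px = mean(rows),
               pixel_count = length(idx))
  }))
}

# All permutations of 1..n.
perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  p <- perms(n - 1L)
  out <- NULL
  for (k in seq_len(n)) {
    out <- rbind(out, cbind(k, p + (p >= k)))
  }
  unname(out)
}

# Exhaustive gated partial-assignment optimum: maximise the number of
# within-gate matches, then minimise total cost. Returns list(n_match,
# cost).
oracle_assignment <- function(cost, gate) {
  nt <- nrow(cost); nd <- ncol(cost)
  gate <- rep_len(gate, nt)
  best <- list(n_match = -1L, cost = Inf)
  recurse <- function(i, used, n_match, total) {
    if (i > nt) {
      if (n_match > best$n_match ||
          (n_match == best$n_match && total < best$cost)) {
        best <<- list(n_match = n_match, cost = total)
      }
      return(invisible())
    }
    recurse(i + 1L, used, n_match, total)  # track i unmatched
    for (j in seq_len(nd)) {
      if (!used[j] && cost[i, j] <= gate[i]) {
        used[j] <- TRUE
        recurse(i + 1L, used, n_match + 1L, total + cost[i, j])
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, nd), 0L, 0)
  best
}

# Exact two-sided rank-sum p by enumeration of all group labellings.
oracle_wilcox_p <- function(a, b) {
  x <- c(a, b)
  n1 <- length(a); n <- length(x)
  r <- rank(x)
  combs <- utils::combn(n, n1)
  W_all <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * (n - n1) / 2
  mean(abs(W_all - mu) >= abs(w - mu) - 1e-9)
}

# Perfect detections straight from simulated ground truth (cm -> px).
truth_detections <- function(truth) {
  s <- truth$scene$px_per_cm
  tr <- truth$trajectories
  data.frame(frame = tr$frame, x_px = tr$x_cm * s - 0.5,
             y_px = tr$y_cm * s - 0.5, grazer_id = tr$grazer_id)
}

# Low-mobility behaviour whose states are still well separated in speed;
# used for non-crossing tracking fixtures.
sluggish_behaviour <- function() {
  behaviour_model(
    transition_matrix = matrix(c(0.80, 0.15, 0.05,
                                 0.25, 0.65, 0.10,
                                 0.20, 0.30, 0.50), 3, byrow = TRUE),
    speed_ranges = list(resting = c(0, 0.25), slow = c(0.5, 1.5),
                        fast = c(4.05, 4.6)),
    turning_kappa = 2)
}

# Widely spaced starting positions in two staggered rows across the tile
# region (the tray is centred and shorter than the flume).
spaced_positions <- function(n, scene) {
  grid_w <- scene$tile_cols * scene$tile_side_cm
  grid_h <- scene$tile_rows * scene$tile_side_cm
  x0 <- (scene$flume_length_cm - grid_w) / 2
  y0 <- (scene$flume_width_cm - grid_h) / 2
  x <- seq(x0 + 1.2, x0 + grid_w - 1.2, length.out = n)
  y <- rep(c(y0 + 1, y0 + grid_h - 1), length.out = n)
  cbind(x, y)
}
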