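# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Truncated-at-zero normal draws (resampling; SD may be 0).
rnorm_trunc0 <- function(n, mean, sd) {
  if (sd < 0) stop("sd must be >= 0")
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < 0)
  while (length(bad) > 0L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < 0)
  }
  x
}

is_rgb_triple <- function(x) {
  is.numeric(x) && length(x) == 3L && all(is.finite(x)) &&
    all(x >= 0) && all(x <= 255)
}

# Rec. 709 luma of an RGB raster (H x W x 3, 0-255) -> H x W matrix.
luminance <- function(frame) {
  stopifnot(length(dim(frame)) == 3L, dim(frame)[3] == 3L)
  0.2126 * frame[, , 1] + 0.7152 * frame[, , 2] + 0.0722 * frame[, , 3]
}
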