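#' Validate a pigment:chlorophyll-a ratio matrix
#'
#' Groups in rows, pigments in columns; all entries non-negative, with a
#' `chlorophyll_a` column identically 1 (ratios are expressed relative to
#' chlorophyll a, so fitted abundances come out in chlorophyll-a
#' equivalents). Zero entries are structural -- a pigment absent from a
#' group -- and are preserved by perturbation and optimisation.
#'
#' @param F numeric matrix with row (group) and column (pigment) names.
#' @return The matrix, invisibly, after validation.
#' @export
validate_ratio_matrix <- function(F) {
  if (!is.matrix(F) || is.null(rownames(F)) || is.null(colnames(F))) {
    stop("ratio matrix needs group rownames and pigment colnames")
  }
  if (any(F < 0)) stop("ratio matrix must be non-negative")
  if (!"chlorophyll_a" %in% colnames(F)) {
    stop("ratio matrix must contain a chlorophyll_a column")
  }
  if (any(abs(F[, "chlorophyll_a"] - 1) > 1e-12)) {
    stop("chlorophyll_a column must be identically 1")
  }
  invisible(F)
}

#' Non-negative least-squares abundance fit
#'
#' For each sample row s of the pigment matrix, solves
#' `min ||s - a F||_2` subject to `a >= 0`, giving chlorophyll-a
#' equivalent abundances of the algal groups. The residual root mean
#' square is taken entrywise over the whole residual matrix,
#' `rms = sqrt(mean((S - A F)^2))`.
#'
#' @param S samples x pigments concentration matrix (non-negative);
#'   column names must match the ratio matrix's pigments.
#' @param F groups x pigments ratio matrix (see
#'   [validate_ratio_matrix()]); must have full row rank.
#' @return list with `abundances` (samples x groups), `residuals`
#'   (samples x pigments) and `rms`.
#' @export
fit_abundances <- function(S, F) {
  validate_ratio_matrix(F)
  S <- as.matrix(S)
  if (any(S < 0)) stop("pigment concentrations must be non-negative")
  if (!is.null(colnames(S))) {
    if (!setequal(colnames(S), colnames(F))) {
      stop("pigment names of S and F differ")
    }
    F <- F[, colnames(S), drop = FALSE]
  } else if (ncol(S) != ncol(F)) {
    stop("S and F must have the same pigments")
  }
  if (qr(F)$rank < nrow(F)) {
    stop("ratio matrix is rank deficient: group pigment signatures are ",
         "linearly dependent and abundances are not identifiable")
  }
  A <- matrix(0, nrow(S), nrow(F),
              dimnames = list(rownames(S), rownames(F)))
  Ct <- t(F)  # pigments x groups design for lsqnonneg
  for (i in seq_len(nrow(S))) {
    s <- S[i, ]
    if (all(s == 0)) next  # a = 0 is the exact solution
    A[i, ] <- pracma::lsqnonneg(Ct, as.numeric(s))$x
  }
  R <- S - A %*% F
  list(abundances = A, residuals = R, rms = sqrt(mean(R^2)))
}

#' Randomly perturb a ratio matrix
#'
#' Each non-zero entry outside the chlorophyll-a column is multiplied by
#' an independent uniform factor in `[1 - magnitude, 1 + magnitude]`;
#' structural zeros and the chlorophyll-a column are untouched.
#'
#' @param F ratio matrix.
#' @param magnitude perturbation half-width, `0 <= magnitude < 1`.
#' @param seed optional seed for a deterministic draw.
#' @return Perturbed ratio matrix.
#' @export
perturb_ratio_matrix <- function(F, magnitude, seed = NULL) {
  validate_ratio_matrix(F)
  if (magnitude < 0 || magnitude >= 1) {
    stop("magnitude must lie in [0, 1)")
  }
  free <- F > 0
  free[, "chlorophyll_a"] <- FALSE
  draw <- function() {
    fac <- matrix(1, nrow(F), ncol(F))
    fac[free] <- stats::runif(sum(free), 1 - magnitude, 1 + magnitude)
    F * fac
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' CHEMTAX-style iterative ratio-matrix optimisation
#'
#' Estimates algal-group contributions to total chlorophyll a while
#' adapting the pigment:chlorophyll-a ratio matrix to the data. Each
#' iteration generates `n_candidates` candidate matrices -- the current
#' matrix itself plus randomly perturbed copies -- fits all of them by
#' non-negative least squares, keeps the
#' `ceiling(keep_fraction * n_candidates)` with the lowest residual rms
#' (6 of 60 under the defaults) and averages them elementwise into the
#' next matrix. If the averaged matrix happens to fit worse than the
#' current one it is discarded in favour of the best kept candidate, so
#' the recorded rms sequence never increases. Iteration stops when both
#' the rms change and the largest elementwise relative ratio change fall
#' below `tol`, or at `max_iter` (flagged as non-converged).
#'
#' @param S samples x pigments concentration matrix.
#' @param F0 initial ratio matrix.
#' @param n_candidates candidate matrices per iteration (including the
#'   unperturbed current matrix).
#' @param keep_fraction fraction of candidates averaged.
#' @param magnitude perturbation half-width (see
#'   [perturb_ratio_matrix()]).
#' @param ratio_bound hard elementwise limit on ratio drift: every free
#'   entry of every candidate matrix is kept within
#'   `[1 - ratio_bound, 1 + ratio_bound]` times its value in `F0`.
#'   Without such a limit the optimiser can drive the marker ratios of a
#'   nearly absent group towards zero, inflating that group's fitted
#'   abundance to absorb noise -- a known failure mode of ratio-adaptive
#'   unmixing. Set to `Inf` to disable.
#' @param tol stability tolerance on rms and relative ratio change.
#' @param max_iter iteration cap.
#' @param seed seed making the whole optimisation deterministic.
#' @return An object of class `chemtax_fit`: `abundances`, `ratio_matrix`
#'   (final), `rms`, `iterations` (data.frame `iteration`, `rms`),
#'   `converged`, `n_kept`.
#' @export
optimize_ratios <- function(S, F0, n_candidates = 60L, keep_fraction = 0.1,
                            magnitude = 0.35, ratio_bound = 0.3,
                            tol = 1e-4, max_iter = 50L, seed = NULL) {
  validate_ratio_matrix(F0)
  n_keep <- ceiling(keep_fraction * n_candidates)
  if (n_keep < 1L) stop("n_candidates * keep_fraction must be >= 1")
  if (ratio_bound <= 0) stop("ratio_bound must be > 0")
  lo <- F0 * max(1 - ratio_bound, 0)
  hi <- F0 * (1 + ratio_bound)
  clamp <- function(Fk) pmin(pmax(Fk, lo), hi)
  run <- function() {
    F_cur <- F0
    fit_cur <- fit_abundances(S, F_cur)
    log_rms <- fit_cur$rms
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      cands <- vector("list", n_candidates)
      cands[[1L]] <- F_cur
      for (k in seq.int(2L, n_candidates)) {
        cands[[k]] <- clamp(perturb_ratio_matrix(F_cur, magnitude))
      }
      rms_k <- vapply(cands, function(Fk) fit_abundances(S, Fk)$rms,
                      numeric(1))
      kept <- order(rms_k)[seq_len(n_keep)]
      F_next <- Reduce(`+`, cands[kept]) / n_keep
      fit_next <- fit_abundances(S, F_next)
      if (fit_next$rms > fit_cur$rms) {
        # averaging can spoil the fit; fall back on the best candidate
        best <- kept[1L]
        F_next <- cands[[best]]
        fit_next <- fit_abundances(S, F_next)
      }
      nz <- F_cur > 0
      rel_change <- if (any(nz)) {
        max(abs(F_next[nz] - F_cur[nz]) / F_cur[nz])
      } else 0
      drms <- abs(fit_cur$rms - fit_next$rms)
      F_cur <- F_next
      fit_cur <- fit_next
      log_rms <- c(log_rms, fit_cur$rms)
      if (drms < tol && rel_change < tol) {
        converged <- TRUE
        break
      }
    }
    structure(list(abundances = fit_cur$abundances, ratio_matrix = F_cur,
                   rms = fit_cur$rms,
                   iterations = data.frame(
                     iteration = seq_along(log_rms) - 1L, rms = log_rms),
                   converged = converged, n_kept = n_keep),
              class = "chemtax_fit")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' @export
print.chemtax_fit <- function(x, ...) {
  cat(sprintf("<chemtax_fit> %d samples x %d groups, rms %.3g (%s, %d iterations)\n",
              nrow(x$abundances), ncol(x$abundances), x$rms,
              if (x$converged) "converged" else "NOT converged",
              nrow(x$iterations) - 1L))
  invisible(x)
}

#' Group composition as percentage of total chlorophyll a
#'
#' @param abundances samples x groups non-negative matrix (chlorophyll-a
#'   equivalents).
#' @return samples x groups matrix of percentages; rows sum to 100.
#'   Samples with zero total abundance are returned as `NA` (composition
#'   undefined).
#' @examples
#' composition_percent(matrix(c(2, 3), 1, dimnames = list(NULL, c("a", "b"))))
#' @export
composition_percent <- function(abundances) {
  A <- as.matrix(abundances)
  if (any(A < 0)) stop("abundances must be non-negative")
  tot <- rowSums(A)
  out <- 100 * A / tot
  out[tot == 0, ] <- NA_real_
  out
}
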