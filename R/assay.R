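#' Example pigment:chlorophyll-a ratio matrices
#'
#' Synthetic two-group ratio matrices (diatoms, chlorophytes) over five
#' pigments, in the style of published freshwater periphyton libraries:
#' one for nutrient-enriched (meso-eutrophic) and one for nutrient-poor
#' (oligotrophic) communities. Fucoxanthin and diadinoxanthin mark
#' diatoms; chlorophyll b and lutein mark chlorophytes. These are
#' editable starting points for [optimize_ratios()], not measured values.
#'
#' @param water `"eutrophic"` or `"oligotrophic"`.
#' @return groups x pigments ratio matrix with a `chlorophyll_a` column
#'   of ones.
#' @export
example_ratio_matrix <- function(water = c("eutrophic", "oligotrophic")) {
  water <- match.arg(water)
  pig <- c("chlorophyll_a", "fucoxanthin", "diadinoxanthin",
           "chlorophyll_b", "lutein")
  F <- if (water == "eutrophic") {
    rbind(diatoms      = c(1, 0.70, 0.14, 0,    0),
          chlorophytes = c(1, 0,    0,    0.33, 0.20))
  } else {
    rbind(diatoms      = c(1, 0.80, 0.10, 0,    0),
          chlorophytes = c(1, 0,    0,    0.38, 0.16))
  }
  colnames(F) <- pig
  validate_ratio_matrix(F)
  F
}

#' Assay configuration for the synthetic experiment
#'
#' Per-treatment distributions of the wet-lab response variables, with
#' defaults matching the factorial phosphorus x grazing experiment the
#' package emulates: molar C:P of 144 +/- 26 (P+) and 316 +/- 68 (P-) at
#' the start of grazing; dry masses of 1.91/0.72 mg cm-2 at the start and
#' 3.18 (P+G-), 2.48 (P+G+), 1.33 (P-G-), 0.23 (P-G+) mg cm-2 at the
#' end; diatom shares of 94 +/- 2 % (P-) and 49 +/- 18 % (P+) of total
#' chlorophyll a. Six replicates at the start (pooled per P level) and
#' three per treatment at the end.
#'
#' @param elemental data.frame with `treatment`, `timepoint`
#'   (start/end), `cp_mean`, `cp_sd`, `dm_mean`, `dm_sd`, `n`.
#' @param composition data.frame with `treatment`, `timepoint`,
#'   `diatom_pct_mean`, `diatom_pct_sd`, `n`.
#' @param ratio_matrices named list of ratio matrices keyed by P level
#'   (`"P+"`, `"P-"`); used both to synthesise pigment samples and as
#'   unmixing start matrices.
#' @param total_chla_mean,total_chla_sd distribution of total
#'   chlorophyll a per sample (concentration units).
#' @param pigment_noise multiplicative log-normal noise SD on pigment
#'   concentrations.
#' @param p_mass_mean_ug,p_mass_sd_ug distribution of the particulate-P
#'   mass from which C mass is back-computed via the drawn C:P.
#' @return list of class `assay_config`.
#' @export
assay_config <- function(elemental = default_elemental_config(),
                         composition = default_composition_config(),
                         ratio_matrices = list(
                           "P+" = example_ratio_matrix("eutrophic"),
                           "P-" = example_ratio_matrix("oligotrophic")),
                         total_chla_mean = 2, total_chla_sd = 0.5,
                         pigment_noise = 0.05,
                         p_mass_mean_ug = 50, p_mass_sd_ug = 5) {
  stopifnot(is.data.frame(elemental), is.data.frame(composition))
  if (any(elemental$cp_sd < 0) || any(elemental$dm_sd < 0) ||
      any(composition$diatom_pct_sd < 0)) {
    stop("SDs must be >= 0")
  }
  if (any(elemental$n < 2) || any(composition$n < 2)) {
    stop("each treatment needs n >= 2 replicates")
  }
  lapply(ratio_matrices, validate_ratio_matrix)
  if (pigment_noise < 0) stop("pigment_noise must be >= 0")
  structure(list(elemental = elemental, composition = composition,
                 ratio_matrices = ratio_matrices,
                 total_chla_mean = total_chla_mean,
                 total_chla_sd = total_chla_sd,
                 pigment_noise = pigment_noise,
                 p_mass_mean_ug = p_mass_mean_ug,
                 p_mass_sd_ug = p_mass_sd_ug),
            class = "assay_config")
}

#' @rdname assay_config
#' @export
default_elemental_config <- function() {
  data.frame(
    treatment = c("P+", "P-", "P+G-", "P+G+", "P-G-", "P-G+"),
    timepoint = c("start", "start", rep("end", 4)),
    cp_mean = c(144, 316, 144, 144, 316, 316),
    cp_sd = c(26, 68, 26, 26, 68, 68),
    dm_mean = c(1.91, 0.72, 3.18, 2.48, 1.33, 0.23),
    dm_sd = c(0.15, 0.29, 0.38, 0.13, 0.11, 0.06),
    n = c(6L, 6L, 3L, 3L, 3L, 3L))
}

#' @rdname assay_config
#' @export
default_composition_config <- function() {
  data.frame(
    treatment = c("P+", "P-", "P+G-", "P+G+", "P-G-", "P-G+"),
    timepoint = c("start", "start", rep("end", 4)),
    diatom_pct_mean = c(49, 94, 49, 49, 94, 94),
    diatom_pct_sd = c(18, 2, 18, 18, 2, 2),
    n = c(6L, 6L, 3L, 3L, 3L, 3L))
}

p_level <- function(treatment) {
  ifelse(grepl("^P\\+", treatment), "P+", "P-")
}

#' Synthesise pigment samples from known group abundances
#'
#' `S = A F` with independent multiplicative log-normal noise,
#' `S_ij <- S_ij * exp(rnorm(1, 0, noise))`; with `noise = 0` the
#' construction is exact, which makes unmixing recoverable by a direct
#' oracle.
#'
#' @param abundances samples x groups non-negative matrix.
#' @param F ratio matrix (groups x pigments).
#' @param noise log-normal noise SD (>= 0).
#' @param seed optional seed.
#' @return samples x pigments concentration matrix.
#' @export
synth_pigment_samples <- function(abundances, F, noise = 0, seed = NULL) {
  validate_ratio_matrix(F)
  A <- as.matrix(abundances)
  stopifnot(ncol(A) == nrow(F), all(A >= 0), noise >= 0)
  gen <- function() {
    S <- A %*% F
    if (noise > 0) {
      S <- S * exp(matrix(stats::rnorm(length(S), 0, noise), nrow(S)))
    }
    S
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Generate synthetic assay tables
#'
#' Draws the elemental table (dry mass, particulate C and P such that the
#' molar C:P follows the configured treatment distribution, truncated at
#' zero), pigment concentration samples constructed from known
#' group-abundance vectors times the P-level ratio matrix plus
#' multiplicative noise, and returns the ground-truth compositions used.
#' Fully deterministic given the seed.
#'
#' @param assay an [assay_config()].
#' @param seed integer seed.
#' @return list of class `assay_tables`: `elemental` (data.frame
#'   `sample`, `treatment`, `timepoint`, `replicate`,
#'   `dry_mass_mg_per_cm2`, `C_mass_ug`, `P_mass_ug`, `cp_true`),
#'   `pigments` (data.frame `sample`, `treatment`, `timepoint` plus one
#'   column per pigment), `compositions` (ground truth: `sample`,
#'   `treatment`, `timepoint`, `total_chla`, `diatoms_pct`,
#'   `chlorophytes_pct` and per-group abundances).
#' @export
generate_assay_tables <- function(assay, seed) {
  stopifnot(inherits(assay, "assay_config"))
  with_seed(seed, {
    el <- assay$elemental
    erows <- lapply(seq_len(nrow(el)), function(i) {
      r <- el[i, ]
      cp <- rnorm_trunc0(r$n, r$cp_mean, r$cp_sd)
      dm <- rnorm_trunc0(r$n, r$dm_mean, r$dm_sd)
      p_ug <- rnorm_trunc0(r$n, assay$p_mass_mean_ug, assay$p_mass_sd_ug)
      c_ug <- cp * p_ug * 12.011 / 30.974  # molar_cp(c_ug, p_ug) == cp
      data.frame(sample = sprintf("%s_%s_%d", r$treatment, r$timepoint,
                                  seq_len(r$n)),
                 treatment = r$treatment, timepoint = r$timepoint,
                 replicate = seq_len(r$n), dry_mass_mg_per_cm2 = dm,
                 C_mass_ug = c_ug, P_mass_ug = p_ug, cp_true = cp)
    })
    elemental <- do.call(rbind, erows)
    rownames(elemental) <- NULL

    co <- assay$composition
    groups <- rownames(assay$ratio_matrices[[1]])
    crows <- list(); prows <- list()
    for (i in seq_len(nrow(co))) {
      r <- co[i, ]
      d_pct <- pmin(pmax(stats::rnorm(r$n, r$diatom_pct_mean,
                                      r$diatom_pct_sd), 0), 100)
      chla <- rnorm_trunc0(r$n, assay$total_chla_mean, assay$total_chla_sd)
      A <- cbind(diatoms = chla * d_pct / 100,
                 chlorophytes = chla * (100 - d_pct) / 100)
      colnames(A) <- groups
      F <- assay$ratio_matrices[[p_level(r$treatment)]]
      S <- synth_pigment_samples(A, F, noise = assay$pigment_noise)
      ids <- sprintf("%s_%s_%d", r$treatment, r$timepoint, seq_len(r$n))
      crows[[i]] <- data.frame(sample = ids, treatment = r$treatment,
                               timepoint = r$timepoint, total_chla = chla,
                               diatoms_pct = d_pct,
                               chlorophytes_pct = 100 - d_pct, A)
      prows[[i]] <- data.frame(sample = ids, treatment = r$treatment,
                               timepoint = r$timepoint, S,
                               check.names = FALSE)
    }
    compositions <- do.call(rbind, crows)
    pigments <- do.call(rbind, prows)
    rownames(compositions) <- rownames(pigments) <- NULL
    structure(list(elemental = elemental, pigments = pigments,
                   compositions = compositions, seed = seed),
              class = "assay_tables")
  })
}

#' Pigment matrix from an assay pigment table
#'
#' @param pigments the `pigments` data.frame of [generate_assay_tables()]
#'   (or a CSV read of it).
#' @param treatment,timepoint optional filters.
#' @return numeric samples x pigments matrix with sample rownames.
#' @export
pigment_matrix <- function(pigments, treatment = NULL, timepoint = NULL) {
  d <- pigments
  if (!is.null(treatment)) d <- d[d$treatment %in% treatment, , drop = FALSE]
  if (!is.null(timepoint)) d <- d[d$timepoint %in% timepoint, , drop = FALSE]
  meta <- c("sample", "treatment", "timepoint")
  m <- as.matrix(d[, setdiff(names(d), meta), drop = FALSE])
  rownames(m) <- d$sample
  m
}
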