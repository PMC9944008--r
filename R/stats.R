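#' Molar carbon-to-phosphorus ratio
#'
#' `(C / 12.011) / (P / 30.974)` from mass amounts in the same unit;
#' lower values indicate more phosphorus-rich (higher-quality) periphyton.
#'
#' @param C_mass_ug,P_mass_ug carbon and phosphorus masses (vectorised);
#'   P must be strictly positive.
#' @return molar C:P ratio.
#' @examples
#' molar_cp(12.011, 30.974)  # 1
#' @export
molar_cp <- function(C_mass_ug, P_mass_ug) {
  if (any(P_mass_ug <= 0)) stop("P mass must be > 0 (ratio undefined)")
  if (any(C_mass_ug < 0)) stop("C mass must be >= 0")
  (C_mass_ug / 12.011) / (P_mass_ug / 30.974)
}

#' Percent reduction relative to a control
#'
#' @param control_mean control mean (> 0).
#' @param treated_mean treated mean.
#' @return `100 * (control - treated) / control`.
#' @examples
#' round(percent_reduction(1.33, 0.23))  # 83
#' round(percent_reduction(3.18, 2.48))  # 22
#' @export
percent_reduction <- function(control_mean, treated_mean) {
  if (any(control_mean <= 0)) stop("control_mean must be > 0")
  100 * (control_mean - treated_mean) / control_mean
}

#' Per-capita grazing rate from dry-mass difference
#'
#' The biomass removed by grazing is the dry-mass areal difference
#' between grazer-free and grazed flumes times the substrate area,
#' converted from mg to ug and divided by the number of grazers and the
#' grazing duration.
#'
#' @param control_mean_dm_mg_cm2 mean dry mass in grazer-free flumes
#'   (mg/cm2).
#' @param grazed_dm_mg_cm2 dry mass in the grazed flume (mg/cm2).
#' @param substrate_cm2 substrate area (cm2).
#' @param n_grazers grazers per flume (>= 1).
#' @param duration_h grazing duration (h, > 0).
#' @return grazing rate in ug h^-1 individual^-1; a negative dry-mass
#'   difference is returned as 0 with a warning.
#' @examples
#' grazing_rate(1.33, 0.23, 158.7, 8, 336)  # ~64.9
#' @export
grazing_rate <- function(control_mean_dm_mg_cm2, grazed_dm_mg_cm2,
                         substrate_cm2, n_grazers, duration_h) {
  if (duration_h <= 0) stop("duration_h must be > 0")
  if (n_grazers < 1) stop("n_grazers must be >= 1")
  if (substrate_cm2 <= 0) stop("substrate_cm2 must be > 0")
  diff_dm <- control_mean_dm_mg_cm2 - grazed_dm_mg_cm2
  if (any(diff_dm < 0)) {
    warning("grazed dry mass exceeds the control mean; rate truncated at 0")
    diff_dm <- pmax(diff_dm, 0)
  }
  diff_dm * 1000 * substrate_cm2 / (n_grazers * duration_h)
}

summary_stats <- function(x) {
  if (is.list(x) && all(c("mean", "sd", "n") %in% names(x))) {
    if (x$n < 2) stop("summary groups need n >= 2")
    if (x$sd < 0) stop("SD must be >= 0")
    list(mean = x$mean, sd = x$sd, n = x$n, raw = NULL)
  } else if (is.numeric(x)) {
    if (length(x) < 2) stop("raw groups need n >= 2")
    list(mean = mean(x), sd = stats::sd(x), n = length(x), raw = x)
  } else {
    stop("groups must be numeric vectors or list(mean, sd, n)")
  }
}

#' Compare two groups (t-tests and Wilcoxon rank sum)
#'
#' Student's pooled-variance t, Welch's t (Satterthwaite df), or the
#' Wilcoxon-Mann-Whitney rank-sum test. Groups may be raw numeric
#' vectors, or -- for the t methods -- summary statistics
#' `list(mean, sd, n)`, which makes published tests reproducible when
#' raw data are unavailable. The Wilcoxon branch reports both the exact
#' two-sided p (used whenever `min(n1, n2) <= 8` and there are no ties)
#' and the normal approximation without continuity correction.
#'
#' @param a,b numeric vectors or `list(mean, sd, n)` summaries.
#' @param method `"student"`, `"welch"` or `"wilcoxon"`.
#' @return list of class `group_test`: `method`, `statistic`, `df`
#'   (`NA` for wilcoxon), `p_value`, `summaries`, and for wilcoxon also
#'   `p_exact` / `p_approx`. A degenerate t (zero variance in both
#'   groups, equal means) is reported with `statistic = NA`.
#' @examples
#' compare_two_groups(list(mean = 27741, sd = 1718, n = 3),
#'                    list(mean = 6550, sd = 2380, n = 3),
#'                    method = "student")
#' @export
compare_two_groups <- function(a, b,
                               method = c("student", "welch", "wilcoxon")) {
  method <- match.arg(method)
  sa <- summary_stats(a)
  sb <- summary_stats(b)
  out <- list(method = method,
              summaries = data.frame(
                group = c("a", "b"), mean = c(sa$mean, sb$mean),
                sd = c(sa$sd, sb$sd), n = c(sa$n, sb$n)))
  if (method == "wilcoxon") {
    if (is.null(sa$raw) || is.null(sb$raw)) {
      stop("wilcoxon requires raw data, not summaries")
    }
    W <- unname(stats::wilcox.test(sa$raw, sb$raw, exact = FALSE)$statistic)
    ties <- anyDuplicated(c(sa$raw, sb$raw)) > 0
    p_exact <- if (!ties) {
      stats::wilcox.test(sa$raw, sb$raw, exact = TRUE)$p.value
    } else NA_real_
    p_approx <- stats::wilcox.test(sa$raw, sb$raw, exact = FALSE,
                                   correct = FALSE)$p.value
    use_exact <- !is.na(p_exact) && min(sa$n, sb$n) <= 8
    out$statistic <- W
    out$df <- NA_real_
    out$p_exact <- p_exact
    out$p_approx <- p_approx
    out$p_value <- if (use_exact) p_exact else p_approx
    class(out) <- "group_test"
    return(out)
  }
  if (method == "student") {
    df <- sa$n + sb$n - 2
    sp2 <- ((sa$n - 1) * sa$sd^2 + (sb$n - 1) * sb$sd^2) / df
    se <- sqrt(sp2 * (1 / sa$n + 1 / sb$n))
  } else {
    va <- sa$sd^2 / sa$n
    vb <- sb$sd^2 / sb$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (sa$n - 1) + vb^2 / (sb$n - 1))
  }
  if (se == 0) {
    out$statistic <- NA_real_
    out$df <- df
    out$p_value <- NA_real_
    out$note <- "zero variance in both groups; t undefined"
  } else {
    t_stat <- (sa$mean - sb$mean) / se
    out$statistic <- t_stat
    out$df <- df
    out$p_value <- 2 * stats::pt(-abs(t_stat), df)
  }
  class(out) <- "group_test"
  out
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("<group_test> %s: statistic = %s, df = %s, p = %s\n",
              x$method, format(x$statistic, digits = 4),
              format(x$df, digits = 4), format(x$p_value, digits = 3)))
  invisible(x)
}

#' Balanced two-way factorial ANOVA with Tukey HSD
#'
#' Fits `response ~ A * B` on a balanced 2 x 2 design (type-I and type-II
#' sums of squares coincide there) and runs Tukey's HSD over the four
#' cell means using the studentized range with the residual df.
#'
#' @param data data.frame.
#' @param response,factor_a,factor_b column names; the factors must each
#'   have exactly two levels with an equal number (>= 2) of replicates in
#'   every cell.
#' @return list of class `factorial_anova`: `table` (data.frame `term`,
#'   `df`, `sum_sq`, `mean_sq`, `F`, `p`), `tukey` (pairwise cell
#'   contrasts with adjusted p), and the underlying `aov` fit.
#' @export
factorial_anova <- function(data, response, factor_a, factor_b) {
  y <- data[[response]]
  A <- factor(data[[factor_a]])
  B <- factor(data[[factor_b]])
  if (nlevels(A) != 2L || nlevels(B) != 2L) {
    stop("both factors must have exactly two levels")
  }
  tab <- table(A, B)
  if (length(unique(as.vector(tab))) != 1L || any(tab < 2L)) {
    stop("design must be balanced with >= 2 replicates per cell")
  }
  d <- data.frame(y = y, A = A, B = B)
  fit <- stats::aov(y ~ A * B, data = d)
  sm <- summary(fit)[[1]]
  terms <- trimws(rownames(sm))
  table_out <- data.frame(
    term = c(factor_a, factor_b,
             paste(factor_a, factor_b, sep = ":"), "Residuals"),
    df = sm$Df, sum_sq = sm$`Sum Sq`, mean_sq = sm$`Mean Sq`,
    F = sm$`F value`, p = sm$`Pr(>F)`)[match(c("A", "B", "A:B", "Residuals"),
                                             terms), ]
  rownames(table_out) <- NULL
  cell <- interaction(A, B, sep = ":")
  fit_cells <- stats::aov(y ~ cell, data = data.frame(y = y, cell = cell))
  tk <- stats::TukeyHSD(fit_cells)$cell
  tukey <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"])
  rownames(tukey) <- NULL
  structure(list(table = table_out, tukey = tukey, fit = fit),
            class = "factorial_anova")
}

#' @export
print.factorial_anova <- function(x, ...) {
  cat("<factorial_anova>\n")
  print(x$table, digits = 4)
  invisible(x)
}

#' Normality and homoscedasticity checks
#'
#' Shapiro-Wilk per group (skipped with a notice for n < 3 or constant
#' samples) and Levene's test across groups with the mean as centre.
#'
#' @param groups named list of numeric vectors.
#' @return list with `shapiro` (data.frame `group`, `n`, `W`, `p`,
#'   `note`) and `levene` (data.frame `F`, `df1`, `df2`, `p`).
#' @export
assumption_checks <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups))) names(groups) <- seq_along(groups)
  sh <- do.call(rbind, lapply(names(groups), function(g) {
    x <- groups[[g]]
    if (length(x) < 3L) {
      data.frame(group = g, n = length(x), W = NA_real_, p = NA_real_,
                 note = "n < 3: Shapiro-Wilk skipped")
    } else if (stats::sd(x) == 0) {
      data.frame(group = g, n = length(x), W = NA_real_, p = NA_real_,
                 note = "constant sample: Shapiro-Wilk undefined")
    } else {
      s <- stats::shapiro.test(x)
      data.frame(group = g, n = length(x), W = unname(s$statistic),
                 p = s$p.value, note = "")
    }
  }))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)))
  lev <- car::leveneTest(y, g, center = mean)
  levene <- data.frame(F = lev$`F value`[1], df1 = lev$Df[1],
                       df2 = lev$Df[2], p = lev$`Pr(>F)`[1])
  list(shapiro = sh, levene = levene)
}
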