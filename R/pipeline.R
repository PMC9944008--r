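#' Behaviour models contrasted by nutrient level
#'
#' Default movement models for the two phosphorus levels: on
#' phosphorus-enriched biofilm grazers rest most of the time, on
#' phosphorus-poor biofilm they move fast more often while searching for
#' food. Used by [run_config()].
#'
#' @param level `"P+"` or `"P-"`.
#' @return a [behaviour_model()].
#' @export
default_behaviour <- function(level = c("P+", "P-")) {
  level <- match.arg(level)
  if (level == "P+") {
    behaviour_model(matrix(c(0.92, 0.06, 0.02,
                             0.30, 0.60, 0.10,
                             0.25, 0.25, 0.50), 3, byrow = TRUE))
  } else {
    behaviour_model(matrix(c(0.55, 0.15, 0.30,
                             0.15, 0.55, 0.30,
                             0.10, 0.15, 0.75), 3, byrow = TRUE))
  }
}

#' End-to-end run configuration
#'
#' Bundles everything one reproducible run needs: the flume/treatment
#' layout of the factorial design (default: the full 2 x 2 with three
#' replicate flumes per treatment), the scene template, per-P-level
#' behaviour models, the assay configuration, linking parameters and the
#' grazed-area sampling interval.
#'
#' @param flumes data.frame with `flume_id` and `treatment` (labels from
#'   `{P+G+, P+G-, P-G+, P-G-}`).
#' @param scene a [scene_config()] template applied to every flume
#'   (grazer-free flumes run with `n_grazers = 0`).
#' @param behaviours named list of [behaviour_model()]s keyed by P level.
#' @param assay an [assay_config()].
#' @param area_sample_every_h interval between analysed frames for the
#'   grazed-area series (h); 12 h at experiment scale, shorter for
#'   desk-scale runs.
#' @param link a [link_params()]; by default the gate is three times the
#'   maximal per-interval fast displacement.
#' @return list of class `run_config`.
#' @export
run_config <- function(flumes = default_flume_layout(),
                       scene = scene_config(),
                       behaviours = list("P+" = default_behaviour("P+"),
                                         "P-" = default_behaviour("P-")),
                       assay = assay_config(),
                       area_sample_every_h = 0.5,
                       link = NULL) {
  stopifnot(is.data.frame(flumes),
            all(c("flume_id", "treatment") %in% names(flumes)))
  bad <- setdiff(unique(flumes$treatment),
                 c("P+G+", "P+G-", "P-G+", "P-G-"))
  if (length(bad)) stop("unknown treatment labels: ", paste(bad, collapse = ", "))
  if (is.null(link)) {
    fast_max <- max(vapply(behaviours,
                           function(b) b$speed_ranges$fast[2], numeric(1)))
    step_px <- fast_max * scene$frame_interval_s / 3600 * scene$px_per_cm
    link <- link_params(n_expected = max(scene$n_grazers, 1L),
                        max_step_px = max(3 * step_px, 2))
  }
  structure(list(flumes = flumes, scene = scene, behaviours = behaviours,
                 assay = assay, area_sample_every_h = area_sample_every_h,
                 link = link),
            class = "run_config")
}

#' @rdname run_config
#' @export
default_flume_layout <- function() {
  data.frame(flume_id = sprintf("F%02d", 1:12),
             treatment = rep(c("P+G+", "P+G-", "P-G+", "P-G-"), each = 3))
}

has_grazers <- function(treatment) grepl("G\\+", treatment)

# Process one grazed flume: simulate -> render -> detect -> track ->
# classify -> area. Returns all stage outputs.
process_flume <- function(flume_id, treatment, config, seed) {
  scene <- config$scene
  behaviour <- config$behaviours[[p_level(treatment)]]
  truth <- simulate_trajectories(scene, behaviour, seed = seed)
  rend <- render_frames(truth, scene)
  spec <- colour_spec(scene$marker_rgb)
  exp_area <- pi * (scene$marker_radius_cm * scene$px_per_cm)^2
  detections <- detect_sequence(rend$frames, spec,
                                expected_area_px = exp_area)
  tracks <- link_sequence(detections, config$link,
                          n_frames = scene$n_frames)
  movements <- compute_speeds(tracks, scene$px_per_cm,
                              scene$frame_interval_s, flume_id = flume_id)
  if (nrow(movements)) movements$treatment <- treatment
  # grazed-area series on frames sampled every area_sample_every_h
  every_s <- config$area_sample_every_h * 3600
  pick <- which(rend$times_s %% every_s < scene$frame_interval_s / 2 |
                  seq_along(rend$times_s) == length(rend$times_s))
  pick <- sort(unique(c(pick, length(rend$times_s))))
  calib <- area_calibration(scene$px_per_cm, rend$tile_mask,
                            scene$tile_side_cm)
  base_lum <- sum(c(0.2126, 0.7152, 0.0722) * scene$biofilm_rgb)
  masks <- lapply(pick, function(f) {
    frame <- rend$frames[[f]]
    excl <- dilate_mask(match_colour(frame, spec), 1L)
    segment_grazed(frame, base_lum, calib, exclude_mask = excl)
  })
  area <- area_series(masks, calib, times_h = rend$times_s[pick] / 3600,
                      cumulative = TRUE)
  truth_area <- rend$grazed_px[pick] / scene$px_per_cm^2
  area$truth_grazed_cm2 <- truth_area
  list(flume_id = flume_id, treatment = treatment, truth = truth,
       detections = detections, tracks = tracks, movements = movements,
       area = area, calib = calib)
}

write_csv <- function(d, path) {
  utils::write.csv(d, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes every stage for each flume of the configuration -- simulate,
#' render, detect, track, classify, grazed area for grazed flumes;
#' grazer-free flumes contribute zero movement records and zero grazed
#' area but still enter the assay analyses -- then generates the assay
#' tables, unmixes pigment compositions per phosphorus level, and runs
#' the statistical layer (start-phase t-tests, end-phase two-way ANOVAs,
#' movement-count and grazed-area comparisons, grazing rates). All
#' intermediate tables are written as CSV under `outdir` and listed in a
#' JSON manifest; per-flume seeds are derived from the global seed by
#' fixed offsets so a run is fully reproducible.
#'
#' @param config a [run_config()].
#' @param outdir output directory (created if missing).
#' @param seed global integer seed.
#' @return Invisibly, the manifest list: `files` (named vector of written
#'   paths), `summary` (category counts per treatment, final grazed
#'   fractions, composition means, test results), `errors` (per-flume
#'   failures, if any), `params`, `timings_s`.
#' @export
run_pipeline <- function(config, outdir, seed) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  files <- character(0)
  errors <- list()
  movements_all <- list()
  area_all <- list()
  timings <- c()

  scene <- config$scene
  for (i in seq_len(nrow(config$flumes))) {
    fl <- config$flumes$flume_id[i]
    trt <- config$flumes$treatment[i]
    ts <- proc.time()[["elapsed"]]
    res <- tryCatch({
      if (has_grazers(trt) && scene$n_grazers > 0L) {
        out <- process_flume(fl, trt, config, seed + i)
        files[paste0(fl, "_trajectories")] <-
          write_csv(out$truth$trajectories,
                    file.path(outdir, paste0(fl, "_trajectories.csv")))
        files[paste0(fl, "_detections")] <-
          write_csv(out$detections,
                    file.path(outdir, paste0(fl, "_detections.csv")))
        files[paste0(fl, "_tracks")] <-
          write_csv(as.data.frame(out$tracks),
                    file.path(outdir, paste0(fl, "_tracks.csv")))
        out
      } else {
        # control flume: no grazers, nothing grazed
        tiles <- tile_mask(scene)
        calib <- area_calibration(scene$px_per_cm, tiles,
                                  scene$tile_side_cm)
        times_h <- seq(0, scene$duration_s / 3600,
                       by = config$area_sample_every_h)
        area <- data.frame(time_h = times_h, grazed_px = 0L,
                           grazed_cm2 = 0, fraction_percent = 0,
                           truth_grazed_cm2 = 0)
        list(flume_id = fl, treatment = trt, movements = NULL,
             area = area, calib = calib)
      }
    }, error = function(e) {
      errors[[fl]] <<- conditionMessage(e)
      NULL
    })
    timings[fl] <- proc.time()[["elapsed"]] - ts
    if (is.null(res)) next
    if (!is.null(res$movements) && nrow(res$movements)) {
      movements_all[[fl]] <- res$movements
    }
    res$area$flume_id <- fl
    res$area$treatment <- trt
    area_all[[fl]] <- res$area
    files[paste0(fl, "_area")] <-
      write_csv(res$area, file.path(outdir, paste0(fl, "_area.csv")))
  }

  movements <- do.call(rbind, movements_all)
  if (!is.null(movements)) {
    files["movements"] <- write_csv(movements,
                                    file.path(outdir, "movements.csv"))
  }
  counts <- if (!is.null(movements)) tally_categories(movements) else
    data.frame(flume_id = character(0), treatment = character(0),
               resting = integer(0), slow = integer(0), fast = integer(0),
               total = integer(0))
  files["category_counts"] <- write_csv(counts,
                                        file.path(outdir, "category_counts.csv"))
  areas <- do.call(rbind, area_all)
  if (!is.null(areas)) {
    files["area_series"] <- write_csv(areas,
                                      file.path(outdir, "area_series.csv"))
  }

  # assay layer
  tables <- generate_assay_tables(config$assay, seed + 10000L)
  files["elemental"] <- write_csv(tables$elemental,
                                  file.path(outdir, "elemental.csv"))
  files["pigments"] <- write_csv(tables$pigments,
                                 file.path(outdir, "pigments.csv"))
  files["compositions_truth"] <- write_csv(tables$compositions,
                                           file.path(outdir, "compositions_truth.csv"))

  comp_fit <- list()
  for (lv in c("P+", "P-")) {
    sel <- p_level(tables$pigments$treatment) == lv
    S <- pigment_matrix(tables$pigments[sel, , drop = FALSE])
    fit <- optimize_ratios(S, config$assay$ratio_matrices[[lv]],
                           seed = seed + 20000L + match(lv, c("P+", "P-")))
    pct <- composition_percent(fit$abundances)
    comp_fit[[lv]] <- data.frame(sample = rownames(pct),
                                 treatment = tables$pigments$treatment[sel],
                                 timepoint = tables$pigments$timepoint[sel],
                                 pct, check.names = FALSE)
    files[paste0("ratio_matrix_", gsub("\\+", "plus", gsub("-", "minus", lv)))] <-
      write_csv(data.frame(group = rownames(fit$ratio_matrix),
                           fit$ratio_matrix, check.names = FALSE),
                file.path(outdir, sprintf("ratio_matrix_%s.csv",
                                          if (lv == "P+") "Pplus" else "Pminus")))
  }
  compositions <- do.call(rbind, comp_fit)
  rownames(compositions) <- NULL
  files["compositions_fit"] <- write_csv(compositions,
                                         file.path(outdir, "compositions_fit.csv"))

  stats_res <- pipeline_stats(tables, compositions, counts, areas,
                              config, scene)
  files["stat_tests"] <- write_csv(stats_res$tests,
                                   file.path(outdir, "stat_tests.csv"))
  if (!is.null(stats_res$anova)) {
    files["anova_tables"] <- write_csv(stats_res$anova,
                                       file.path(outdir, "anova_tables.csv"))
  }
  if (!is.null(stats_res$grazing_rates)) {
    files["grazing_rates"] <- write_csv(stats_res$grazing_rates,
                                        file.path(outdir, "grazing_rates.csv"))
  }

  summary <- list(
    category_counts = counts,
    final_grazed = if (!is.null(areas)) {
      do.call(rbind, lapply(split(areas, areas$flume_id), function(d) {
        d[which.max(d$time_h), c("flume_id", "treatment", "grazed_cm2",
                                 "fraction_percent")]
      }))
    },
    composition_means = stats::aggregate(
      compositions[, setdiff(names(compositions),
                             c("sample", "treatment", "timepoint"))],
      by = list(treatment = compositions$treatment,
                timepoint = compositions$timepoint), FUN = mean),
    tests = stats_res$tests)
  manifest <- list(files = files, summary = summary, errors = errors,
                   params = list(seed = seed,
                                 n_flumes = nrow(config$flumes),
                                 n_frames = scene$n_frames,
                                 px_per_cm = scene$px_per_cm,
                                 area_sample_every_h = config$area_sample_every_h),
                   timings_s = round(c(timings,
                                       total = proc.time()[["elapsed"]] - t0), 3))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}

# Statistical layer over the pipeline outputs.
pipeline_stats <- function(tables, compositions, counts, areas, config,
                           scene) {
  tests <- list()
  add_test <- function(name, tt) {
    tests[[length(tests) + 1L]] <<- data.frame(
      test = name, method = tt$method, statistic = tt$statistic,
      df = tt$df, p_value = tt$p_value)
  }
  el <- tables$elemental
  el$cp <- molar_cp(el$C_mass_ug, el$P_mass_ug)
  start <- el[el$timepoint == "start", ]
  by_lv <- split(start, p_level(start$treatment))
  if (all(vapply(by_lv, nrow, integer(1)) >= 2)) {
    add_test("start_cp", compare_two_groups(by_lv[["P+"]]$cp,
                                            by_lv[["P-"]]$cp, "student"))
    add_test("start_dry_mass",
             compare_two_groups(by_lv[["P+"]]$dry_mass_mg_per_cm2,
                                by_lv[["P-"]]$dry_mass_mg_per_cm2,
                                "student"))
  }
  cstart <- compositions[compositions$timepoint == "start", ]
  if (nrow(cstart) >= 4 && "diatoms" %in% names(cstart)) {
    cs <- split(cstart$diatoms, p_level(cstart$treatment))
    if (all(lengths(cs) >= 2)) {
      add_test("start_diatom_pct",
               compare_two_groups(cs[["P+"]], cs[["P-"]], "welch"))
    }
  }
  # end-phase two-way ANOVAs
  end <- el[el$timepoint == "end", ]
  anova_tabs <- NULL
  if (nrow(end) >= 8) {
    end$P <- p_level(end$treatment)
    end$G <- ifelse(has_grazers(end$treatment), "G+", "G-")
    anov <- list()
    for (resp in c("cp", "dry_mass_mg_per_cm2")) {
      fa <- tryCatch(factorial_anova(end, resp, "P", "G"),
                     error = function(e) NULL)
      if (!is.null(fa)) {
        tab <- fa$table
        tab$response <- resp
        anov[[resp]] <- tab
      }
    }
    cend <- compositions[compositions$timepoint == "end", ]
    if (nrow(cend) >= 8 && "diatoms" %in% names(cend)) {
      cend$P <- p_level(cend$treatment)
      cend$G <- ifelse(has_grazers(cend$treatment), "G+", "G-")
      fa <- tryCatch(factorial_anova(cend, "diatoms", "P", "G"),
                     error = function(e) NULL)
      if (!is.null(fa)) {
        tab <- fa$table
        tab$response <- "diatom_pct"
        anov[["diatom_pct"]] <- tab
      }
    }
    if (length(anov)) anova_tabs <- do.call(rbind, anov)
  }
  # movement-count comparisons between grazed treatments
  if (nrow(counts) && "treatment" %in% names(counts)) {
    cg <- split(counts, counts$treatment)
    if (!is.null(cg[["P+G+"]]) && !is.null(cg[["P-G+"]]) &&
        nrow(cg[["P+G+"]]) >= 2 && nrow(cg[["P-G+"]]) >= 2) {
      add_test("resting_detections",
               compare_two_groups(cg[["P+G+"]]$resting,
                                  cg[["P-G+"]]$resting, "student"))
      add_test("slow_detections",
               compare_two_groups(cg[["P+G+"]]$slow,
                                  cg[["P-G+"]]$slow, "wilcoxon"))
      add_test("fast_detections",
               compare_two_groups(cg[["P+G+"]]$fast,
                                  cg[["P-G+"]]$fast, "wilcoxon"))
    }
  }
  # final grazed areas and grazing rates
  rates <- NULL
  if (!is.null(areas)) {
    finals <- do.call(rbind, lapply(split(areas, areas$flume_id),
                                    function(d) d[which.max(d$time_h), ]))
    fg <- split(finals, finals$treatment)
    if (!is.null(fg[["P+G+"]]) && !is.null(fg[["P-G+"]]) &&
        nrow(fg[["P+G+"]]) >= 2 && nrow(fg[["P-G+"]]) >= 2) {
      add_test("final_grazed_area",
               compare_two_groups(fg[["P+G+"]]$grazed_cm2,
                                  fg[["P-G+"]]$grazed_cm2, "student"))
    }
    end_el <- tables$elemental[tables$elemental$timepoint == "end", ]
    duration_h <- scene$duration_s / 3600
    if (nrow(end_el) && duration_h > 0) {
      rr <- list()
      for (lv in c("P+", "P-")) {
        ctrl <- end_el[p_level(end_el$treatment) == lv &
                         !has_grazers(end_el$treatment), ]
        grz <- end_el[p_level(end_el$treatment) == lv &
                        has_grazers(end_el$treatment), ]
        if (nrow(ctrl) && nrow(grz)) {
          sub_cm2 <- tile_total_area(scene$tile_rows * scene$tile_cols -
                                       length(scene$removed_tiles),
                                     scene$tile_side_cm)
          r <- suppressWarnings(grazing_rate(
            mean(ctrl$dry_mass_mg_per_cm2), grz$dry_mass_mg_per_cm2,
            sub_cm2, max(scene$n_grazers, 1L), duration_h))
          rr[[lv]] <- data.frame(p_level = lv, sample = grz$sample,
                                 rate_ug_h_ind = r)
        }
      }
      if (length(rr)) {
        rates <- do.call(rbind, rr)
        rownames(rates) <- NULL
        rs <- split(rates$rate_ug_h_ind, rates$p_level)
        if (all(lengths(rs) >= 2)) {
          add_test("grazing_rate",
                   compare_two_groups(rs[["P+"]], rs[["P-"]], "student"))
        }
      }
    }
  }
  tests <- if (length(tests)) do.call(rbind, tests) else
    data.frame(test = character(0), method = character(0),
               statistic = numeric(0), df = numeric(0),
               p_value = numeric(0))
  rownames(tests) <- NULL
  list(tests = tests, anova = anova_tabs, grazing_rates = rates)
}
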