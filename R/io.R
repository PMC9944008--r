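#' Read a scene configuration from YAML
#'
#' Loads a YAML file whose keys are [scene_config()] arguments (unknown
#' keys are rejected) and builds the validated scene object, so runs can
#' be configured from plain-text files.
#'
#' @param path YAML file.
#' @return a [scene_config()].
#' @export
read_scene_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(scene_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown scene_config keys: ", paste(bad, collapse = ", "))
  }
  do.call(scene_config, vals)
}

#' Write a scene configuration to YAML
#'
#' @param scene a [scene_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scene_config <- function(scene, path) {
  stopifnot(inherits(scene, "scene_config"))
  drop <- c("n_frames")  # derived
  vals <- scene[setdiff(names(scene), drop)]
  vals <- vals[!vapply(vals, is.null, logical(1))]
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' Write ground-truth trajectories as CSV
#'
#' Columns `frame`, `grazer_id`, `x_cm`, `y_cm`, `state`, matching the
#' trajectory table of [simulate_trajectories()].
#'
#' @param truth a `flume_truth`.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(truth, path) {
  stopifnot(inherits(truth, "flume_truth"))
  utils::write.csv(truth$trajectories, path, row.names = FALSE)
  invisible(path)
}
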