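#' Configuration of an end-to-end analysis run
#'
#' Bundles the motion model, the geometry grid and the Monte Carlo settings
#' of a full simulate -> statistics -> coverage -> DVH run.  The default
#' grid crosses lesion radii of 3, 5 and 7 mm with safety margins of 0, 2
#' and 5 mm.
#'
#' @param motion A [motion_model_params()] object.
#' @param radii Lesion radii in mm, all > 0.
#' @param margins Safety margins in mm, all >= 0.
#' @param dvh_points Monte Carlo points per lesion sphere.
#' @param dvh_seed Seed for the DVH point sets.
#' @param per_patient Also write per-patient statistics and DVHs.
#' @param trajectory_file Optional path to an existing trajectory CSV (same
#'   column contract as [write_trajectories()]); when given, it replaces
#'   simulation so real tracking exports can be analysed unchanged.
#' @return An object of class `run_config`.
#' @export
run_config <- function(motion = motion_model_params(),
                       radii = c(3, 5, 7),
                       margins = c(0, 2, 5),
                       dvh_points = 5000,
                       dvh_seed = motion$seed,
                       per_patient = FALSE,
                       trajectory_file = NULL) {
  validate_motion_model_params(motion)
  .check_geometry_grid(radii, margins)
  if (!is.numeric(dvh_points) || length(dvh_points) != 1L ||
      is.na(dvh_points) || dvh_points < 1) {
    stop("`dvh_points` must be a count >= 1", call. = FALSE)
  }
  if (!is.null(trajectory_file) && !file.exists(trajectory_file)) {
    stop("trajectory file not found: ", trajectory_file, call. = FALSE)
  }
  structure(
    list(motion = motion, radii = as.numeric(radii),
         margins = as.numeric(margins),
         dvh_points = as.integer(dvh_points),
         dvh_seed = as.integer(dvh_seed),
         per_patient = isTRUE(per_patient),
         trajectory_file = trajectory_file),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' The YAML file may contain a `motion:` mapping with any
#' [motion_model_params()] field plus the top-level fields of
#' [run_config()]; omitted fields keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known_top <- c("motion", "radii", "margins", "dvh_points", "dvh_seed",
                 "per_patient", "trajectory_file")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown) > 0L) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  motion <- do.call(motion_model_params, as.list(raw$motion))
  args <- raw[setdiff(names(raw), "motion")]
  do.call(run_config, c(list(motion = motion), args))
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a trajectory set, then writes into `output_dir`:
#' the trajectory CSV, the pooled displacement statistics table, raw and
#' rounded-percent coverage tables for both `c_IPL` and `c_SIB`, one gridded
#' DVH CSV per geometry (and per patient when requested), and a JSON run
#' manifest recording the full configuration and sample counts.  Re-running
#' with the same configuration reproduces every CSV byte for byte.
#'
#' @param config A [run_config()] object.
#' @param output_dir Output directory; created if missing.
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a named list of the written file paths.
#' @export
run_pipeline <- function(config, output_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(output_dir)) {
    stop("cannot create output directory: ", output_dir, call. = FALSE)
  }
  say <- function(...) if (!quiet) message(sprintf(...))
  paths <- list()

  if (is.null(config$trajectory_file)) {
    say("simulate: %d patients x %d fractions",
        config$motion$n_patients, config$motion$fractions_per_patient)
    trajectories <- simulate_cohort(config$motion)
  } else {
    say("load: %s", config$trajectory_file)
    trajectories <- read_trajectories(config$trajectory_file)
  }
  say("trajectories: %d samples", nrow(trajectories))
  paths$trajectories <- file.path(output_dir, "trajectories.csv")
  write_trajectories(trajectories, paths$trajectories)

  max_d <- max(radial_distance(trajectories$lat_mm, trajectories$long_mm,
                               trajectories$vert_mm))
  for (m in config$margins) {
    if (m >= max_d) {
      warning(sprintf(
        "margin %g mm is >= the largest recorded displacement (%.2f mm): coverage is trivially complete",
        m, max_d), call. = FALSE)
    }
  }

  say("stats: pooled displacement table")
  paths$displacement_stats <- file.path(output_dir, "displacement_stats.csv")
  readr::write_csv(displacement_table(trajectories),
                   paths$displacement_stats, progress = FALSE)
  if (config$per_patient) {
    paths$displacement_stats_per_patient <-
      file.path(output_dir, "displacement_stats_per_patient.csv")
    readr::write_csv(displacement_table(trajectories, by_patient = TRUE),
                     paths$displacement_stats_per_patient, progress = FALSE)
  }

  say("coverage: %d radii x %d margins",
      length(config$radii), length(config$margins))
  paths$coverage <- file.path(output_dir, "coverage.csv")
  readr::write_csv(coverage_table(trajectories, config$radii,
                                  config$margins),
                   paths$coverage, progress = FALSE)
  for (w in c("c_ipl", "c_sib")) {
    key <- paste0("coverage_", w, "_percent")
    paths[[key]] <- file.path(output_dir, paste0(key, ".csv"))
    readr::write_csv(
      coverage_percent_table(trajectories, config$radii, config$margins,
                             which = w),
      paths[[key]], progress = FALSE)
  }

  say("dvh: %d points per sphere", config$dvh_points)
  for (r_i in seq_along(config$radii)) {
    r <- config$radii[r_i]
    pts <- sample_sphere(r, n = config$dvh_points,
                         seed = derive_stream_seed(config$dvh_seed, r_i, 0L))
    for (m in config$margins) {
      curve <- compute_dvh(pts, trajectories, sphere_geometry(r, m))
      key <- sprintf("dvh_r%g_m%g", r, m)
      paths[[key]] <- file.path(output_dir, paste0(key, ".csv"))
      readr::write_csv(dvh_curve_table(curve), paths[[key]],
                       progress = FALSE)
    }
  }
  if (config$per_patient) {
    per <- dvh_per_patient(trajectories, config$radii, config$margins,
                           n = config$dvh_points, seed = config$dvh_seed)
    for (i in seq_len(nrow(per))) {
      key <- sprintf("dvh_%s_r%g_m%g", per$patient_id[i], per$r_mm[i],
                     per$margin_mm[i])
      paths[[key]] <- file.path(output_dir, paste0(key, ".csv"))
      readr::write_csv(dvh_curve_table(per$curve[[i]]), paths[[key]],
                       progress = FALSE)
    }
  }

  manifest <- list(
    package = "iplmotion",
    version = as.character(utils::packageVersion("iplmotion")),
    config = unclass_config(config),
    n_samples = nrow(trajectories),
    n_patients = length(unique(trajectories$patient_id)),
    n_fractions = nrow(dplyr::distinct(trajectories, .data$patient_id,
                                       .data$fraction_id)),
    files = vapply(paths, basename, character(1))
  )
  paths$manifest <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  say("done: %d files in %s", length(paths), output_dir)
  invisible(paths)
}

unclass_config <- function(config) {
  out <- unclass(config)
  out$motion <- unclass(out$motion)
  out
}
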