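#' Validate a trajectory set
#'
#' A trajectory set is the pooled unit of all downstream analysis: a tibble
#' with one row per tracked position sample and columns `patient_id`,
#' `fraction_id`, `t_seconds`, `lat_mm`, `long_mm`, `vert_mm`.
#' Displacements are in mm relative to the start-of-fraction position;
#' elapsed time must be non-negative and non-decreasing within each
#' fraction.
#'
#' @param x A data frame with the trajectory columns.
#' @return `x` as a tibble, invisibly validated; errors describe the first
#'   violated contract.
#' @export
as_trajectory_set <- function(x) {
  required <- c("patient_id", "fraction_id", "t_seconds",
                "lat_mm", "long_mm", "vert_mm")
  if (!is.data.frame(x)) stop("trajectory set must be a data frame",
                              call. = FALSE)
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L) {
    stop("trajectory set is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- tibble::as_tibble(x)[required]
  x$patient_id <- as.character(x$patient_id)
  x$fraction_id <- as.character(x$fraction_id)
  num_cols <- c("t_seconds", "lat_mm", "long_mm", "vert_mm")
  for (col in num_cols) {
    if (!is.numeric(x[[col]]) || anyNA(x[[col]])) {
      stop("column `", col, "` must be numeric without missing values",
           call. = FALSE)
    }
  }
  if (nrow(x) == 0L) stop("trajectory set is empty", call. = FALSE)
  if (any(x$t_seconds < 0)) {
    stop("`t_seconds` must be non-negative", call. = FALSE)
  }
  bad <- x |>
    dplyr::group_by(.data$patient_id, .data$fraction_id) |>
    dplyr::summarise(ok = !is.unsorted(.data$t_seconds), .groups = "drop")
  if (!all(bad$ok)) {
    stop("`t_seconds` must be non-decreasing within each fraction",
         call. = FALSE)
  }
  x
}

#' Read / write trajectory files
#'
#' Trajectory files are plain CSV with a mandatory header and columns
#' `patient_id, fraction_id, t_seconds, lat_mm, long_mm, vert_mm`.  Real
#' tracking exports in the same column contract can be analysed in place of
#' simulated cohorts.
#'
#' @param path File path.
#' @return `read_trajectories()` returns a validated trajectory set tibble.
#' @export
read_trajectories <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_trajectory_set(x)
}

#' @rdname read_trajectories
#' @param trajectories A trajectory set ([as_trajectory_set()]).
#' @return `write_trajectories()` returns `path` invisibly.
#' @export
write_trajectories <- function(trajectories, path) {
  trajectories <- as_trajectory_set(trajectories)
  readr::write_csv(trajectories, path, progress = FALSE)
  invisible(path)
}
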