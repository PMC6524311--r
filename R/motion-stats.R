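#' Radial (Euclidean 3D) displacement
#'
#' The vector length of a displacement: `sqrt(lat^2 + long^2 + vert^2)`.
#' Always recomputed from the per-axis components, never stored.
#'
#' @param lat,long,vert Signed per-axis displacements in mm (vectorized).
#' @return Non-negative radial distances in mm.
#' @examples
#' radial_distance(3, 4, 0)  # 5
#' @export
radial_distance <- function(lat, long, vert) {
  sqrt(lat^2 + long^2 + vert^2)
}

# statistic labels shared by all report tables; coverage tables drop rms
.stat_names <- c("mean", "std", "min", "q05", "q25", "median",
                 "q75", "q95", "max", "rms")

#' Summary statistics of a displacement (or coverage) sample
#'
#' Computes the ten statistics used throughout the report tables: mean,
#' standard deviation, minimum, 5/25/50/75/95 percent quantiles, maximum
#' and root mean square.  Quantiles use linear interpolation between order
#' statistics (`stats::quantile()` type 7), fixed so results are
#' reproducible bit for bit.
#'
#' @param values Non-empty numeric vector without missing values.
#' @return A one-row tibble with columns `mean`, `std`, `min`, `q05`,
#'   `q25`, `median`, `q75`, `q95`, `max`, `rms`.
#' @examples
#' summarize_values(c(2, 2, 2, 2))
#' @export
summarize_values <- function(values) {
  if (length(values) == 0L) {
    stop("cannot summarize an empty sample", call. = FALSE)
  }
  if (!is.numeric(values) || anyNA(values)) {
    stop("`values` must be numeric without missing values", call. = FALSE)
  }
  q <- stats::quantile(values, probs = c(0.05, 0.25, 0.5, 0.75, 0.95),
                       type = 7, names = FALSE)
  tibble::tibble(
    mean = mean(values),
    std = if (length(values) > 1L) stats::sd(values) else 0,
    min = min(values),
    q05 = q[1L], q25 = q[2L], median = q[3L], q75 = q[4L], q95 = q[5L],
    max = max(values),
    rms = sqrt(mean(values^2))
  )
}

#' Displacement summary table
#'
#' Pools all samples of a trajectory set with equal weight — every sample
#' counts once regardless of fraction length or patient — and summarizes the
#' signed longitudinal, lateral and vertical displacements plus the radial
#' (Euclidean 3D) distance.  With `by_patient = TRUE` one such row-set is
#' produced per patient.
#'
#' @param trajectories A trajectory set ([as_trajectory_set()]).
#' @param by_patient Stratify by patient instead of pooling the cohort.
#' @param include_anchor Include each fraction's `t = 0` anchor sample
#'   (which is (0,0,0) by construction for simulated data).  Anchors are
#'   recorded positions and are included by default.
#' @return A tidy tibble with a `statistic` column and columns
#'   `longitudinal`, `lateral`, `vertical`, `radial` (all mm); with
#'   `by_patient = TRUE` an additional leading `patient_id` column.
#' @examples
#' ts <- simulate_cohort(motion_model_params(n_patients = 2,
#'                                           fractions_per_patient = 2))
#' displacement_table(ts)
#' @export
displacement_table <- function(trajectories, by_patient = FALSE,
                               include_anchor = TRUE) {
  trajectories <- as_trajectory_set(trajectories)
  if (!include_anchor) {
    trajectories <- dplyr::filter(trajectories, .data$t_seconds > 0)
    if (nrow(trajectories) == 0L) {
      stop("no samples left after dropping t = 0 anchors", call. = FALSE)
    }
  }
  one_block <- function(df) {
    axes <- list(
      longitudinal = df$long_mm,
      lateral = df$lat_mm,
      vertical = df$vert_mm,
      radial = radial_distance(df$lat_mm, df$long_mm, df$vert_mm)
    )
    cols <- lapply(axes, function(v) unname(unlist(summarize_values(v))))
    tibble::tibble(statistic = .stat_names, !!!cols)
  }
  if (!by_patient) {
    return(one_block(trajectories))
  }
  trajectories |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(~ one_block(.x)) |>
    dplyr::ungroup()
}

#' Per-patient mean radial displacement
#'
#' One row per patient with the number of samples and the mean radial
#' displacement, the quantity used to rank patients by motility.
#'
#' @inheritParams displacement_table
#' @return A tibble with columns `patient_id`, `n_samples`,
#'   `mean_radial_mm`.
#' @export
patient_motility_table <- function(trajectories) {
  trajectories <- as_trajectory_set(trajectories)
  trajectories |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      mean_radial_mm = mean(radial_distance(.data$lat_mm, .data$long_mm,
                                            .data$vert_mm)),
      .groups = "drop"
    )
}
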