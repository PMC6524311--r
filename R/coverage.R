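#' Boost geometry: lesion radius and safety margin
#'
#' The intraprostatic lesion (IPL) is idealized as a sphere of radius `r`;
#' the simultaneous integrated boost (SIB) dose as constant within a
#' concentric sphere of radius `r+m` and zero outside, `m` the safety
#' margin.
#'
#' @param r Lesion radius in mm, > 0.
#' @param m Safety margin in mm, >= 0.
#' @return An object of class `sphere_geometry`.
#' @examples
#' sphere_geometry(5, 2)
#' @export
sphere_geometry <- function(r, m = 0) {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0) {
    stop("`r` must be a single positive number (mm)", call. = FALSE)
  }
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m) || m < 0) {
    stop("`m` must be a single non-negative number (mm)", call. = FALSE)
  }
  structure(list(r = r, m = m), class = "sphere_geometry")
}

#' @export
print.sphere_geometry <- function(x, ...) {
  cat(sprintf("<sphere_geometry> IPL r = %g mm, margin m = %g mm (SIB radius %g mm)\n",
              x$r, x$m, x$r + x$m))
  invisible(x)
}

.check_distance <- function(d) {
  if (!is.numeric(d) || anyNA(d)) {
    stop("`d` must be numeric without missing values", call. = FALSE)
  }
  if (any(d < 0)) stop("`d` must be non-negative (mm)", call. = FALSE)
  d
}

#' Overlap volume of the lesion and the displaced boost sphere
#'
#' Closed-form volume of the lens-shaped intersection of the IPL sphere
#' (radius `r`) with the SIB sphere (radius `r+m`) when their centres are
#' a distance `d` apart:
#' \deqn{V = \frac{\pi}{12 d} (2r + m - d)^2 \left(d^2 + 2 d (2r + m) - 3 m^2\right)}
#' for `m < d < 2r + m`; the full lesion volume \eqn{4\pi r^3/3} when the
#' lesion is entirely inside the boost (`d <= m`); 0 when the spheres are
#' disjoint (`d >= 2r + m`).  The expression is continuous across both
#' branch points.
#'
#' @param geom A [sphere_geometry()].
#' @param d Centre-to-centre distance(s) in mm, vectorized.
#' @return Overlap volume(s) in mm^3.
#' @examples
#' overlap_volume(sphere_geometry(5, 2), 2)  # full lesion: 4/3*pi*125
#' @export
overlap_volume <- function(geom, d) {
  stopifnot(inherits(geom, "sphere_geometry"))
  .check_distance(d)
  r <- geom$r
  m <- geom$m
  v <- numeric(length(d))
  full <- d <= m
  lens <- d > m & d < 2 * r + m
  v[full] <- 4 / 3 * pi * r^3
  dl <- d[lens]
  v[lens] <- pi / (12 * dl) * (2 * r + m - dl)^2 *
    (dl^2 + 2 * dl * (2 * r + m) - 3 * m^2)
  v
}

#' Coverage of the lesion by the displaced boost
#'
#' Fraction `c_IPL` of the IPL volume that lies inside the SIB sphere when
#' the prostate is displaced by `d`: 1 for `d <= m`, 0 for `d >= 2r + m`,
#' otherwise the lens overlap volume divided by the lesion volume
#' \eqn{4\pi r^3/3}.  Continuous and non-increasing in `d`.
#'
#' @inheritParams overlap_volume
#' @return Coverage fraction(s) in \[0, 1\].
#' @examples
#' coverage_ipl(sphere_geometry(5, 0), 5)  # 0.3125
#' @export
coverage_ipl <- function(geom, d) {
  overlap_volume(geom, d) / (4 / 3 * pi * geom$r^3)
}

#' Occupancy of the boost by the displaced lesion
#'
#' Fraction `c_SIB` of the SIB volume occupied by the IPL, the dose
#' efficiency of the boost.  For every displacement,
#' `c_SIB = r^3 / (r + m)^3 * c_IPL` exactly: even a perfectly centred
#' lesion (`d = 0`) fills only the cubic volume ratio of the boost.
#'
#' @inheritParams overlap_volume
#' @return Occupancy fraction(s) in \[0, 1\], bounded by `r^3/(r+m)^3`.
#' @examples
#' coverage_sib(sphere_geometry(5, 2), 0)  # 125/343, prints as 36%
#' @export
coverage_sib <- function(geom, d) {
  geom$r^3 / (geom$r + geom$m)^3 * coverage_ipl(geom, d)
}

#' Round a fraction to integer percent, half away from zero
#'
#' Report tables print coverage as integer percentages with halves rounded
#' up (0.125 -> 13%), unlike R's banker's rounding.
#'
#' @param x Fractions in \[0, 1\] (vectorized).
#' @return Integer percentages.
#' @examples
#' percent_half_up(125 / 1000)  # 13
#' @export
percent_half_up <- function(x) {
  as.integer(floor(100 * x + 0.5))
}

#' Per-sample coverage of a trajectory set
#'
#' Evaluates `c_IPL` and `c_SIB` at the radial displacement of every pooled
#' sample, for every combination of lesion radius and safety margin.
#'
#' @param trajectories A trajectory set ([as_trajectory_set()]).
#' @param radii Lesion radii in mm.
#' @param margins Safety margins in mm.
#' @return A tibble with columns `r_mm`, `margin_mm`, `patient_id`,
#'   `fraction_id`, `t_seconds`, `d_mm`, `c_ipl`, `c_sib`.
#' @export
coverage_samples <- function(trajectories, radii = c(3, 5, 7),
                             margins = c(0, 2, 5)) {
  trajectories <- as_trajectory_set(trajectories)
  .check_geometry_grid(radii, margins)
  d <- radial_distance(trajectories$lat_mm, trajectories$long_mm,
                       trajectories$vert_mm)
  grid <- tidyr::expand_grid(margin_mm = margins, r_mm = radii)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    geom <- sphere_geometry(grid$r_mm[i], grid$margin_mm[i])
    tibble::tibble(
      r_mm = grid$r_mm[i], margin_mm = grid$margin_mm[i],
      patient_id = trajectories$patient_id,
      fraction_id = trajectories$fraction_id,
      t_seconds = trajectories$t_seconds,
      d_mm = d,
      c_ipl = coverage_ipl(geom, d),
      c_sib = coverage_sib(geom, d)
    )
  })
  dplyr::bind_rows(out)
}

.check_geometry_grid <- function(radii, margins) {
  if (length(radii) == 0L || !is.numeric(radii) || any(radii <= 0)) {
    stop("`radii` must be positive numbers (mm)", call. = FALSE)
  }
  if (length(margins) == 0L || !is.numeric(margins) || any(margins < 0)) {
    stop("`margins` must be non-negative numbers (mm)", call. = FALSE)
  }
  invisible(NULL)
}

#' Coverage summary tables
#'
#' Summarizes the per-sample coverage fractions over all pooled samples for
#' each geometry: mean, standard deviation, minimum, 5/25/50/75/95 percent
#' quantiles and maximum — the nine statistics of the coverage report
#' tables, for both `c_IPL` (how much of the lesion gets boost dose) and
#' `c_SIB` (how much of the boost dose hits the lesion).
#'
#' @inheritParams coverage_samples
#' @return A long tibble with columns `r_mm`, `margin_mm`, `statistic`,
#'   `c_ipl`, `c_sib` (raw fractions).  Use [coverage_percent_table()] for
#'   the rounded-percent presentation.
#' @examples
#' ts <- simulate_cohort(motion_model_params(n_patients = 2,
#'                                           fractions_per_patient = 2))
#' coverage_table(ts, radii = 5, margins = c(0, 2))
#' @export
coverage_table <- function(trajectories, radii = c(3, 5, 7),
                           margins = c(0, 2, 5)) {
  samples <- coverage_samples(trajectories, radii, margins)
  stats9 <- setdiff(.stat_names, "rms")
  samples |>
    dplyr::group_by(.data$margin_mm, .data$r_mm) |>
    dplyr::reframe(
      statistic = stats9,
      c_ipl = unname(unlist(summarize_values(.data$c_ipl)[stats9])),
      c_sib = unname(unlist(summarize_values(.data$c_sib)[stats9]))
    ) |>
    dplyr::select("r_mm", "margin_mm", "statistic", "c_ipl", "c_sib")
}

#' @rdname coverage_table
#' @param which `"c_ipl"` or `"c_sib"`: which fraction to present.
#' @return `coverage_percent_table()` returns a wide tibble (statistic rows,
#'   one integer-percent column per margin/radius combination).
#' @export
coverage_percent_table <- function(trajectories, radii = c(3, 5, 7),
                                   margins = c(0, 2, 5),
                                   which = c("c_ipl", "c_sib")) {
  which <- match.arg(which)
  coverage_table(trajectories, radii, margins) |>
    dplyr::mutate(percent = percent_half_up(.data[[which]]),
                  column = sprintf("m%g_r%g", .data$margin_mm, .data$r_mm)) |>
    dplyr::select("statistic", "column", "percent") |>
    tidyr::pivot_wider(names_from = "column", values_from = "percent")
}
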