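#' Uniform Monte Carlo sample of the lesion sphere
#'
#' Draws `n` points uniformly in the ball of radius `r` by an isotropic
#' direction (normalized Gaussian triple) and a radius `r*U^(1/3)`.  The
#' scheme is fixed so that a seed always reproduces the same point set.
#'
#' @param r Sphere radius in mm, > 0.
#' @param n Number of points, >= 1 (default 5000).
#' @param seed RNG seed; the global RNG state is left untouched.
#' @return An object of class `sphere_points`: list with `points` (an
#'   `n x 3` matrix of coordinates in mm), `r`, `n`, `seed`.
#' @examples
#' pts <- sample_sphere(5, n = 100, seed = 1)
#' max(sqrt(rowSums(pts$points^2)))  # <= 5
#' @export
sample_sphere <- function(r, n = 5000, seed = 1L) {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0) {
    stop("`r` must be a single positive number (mm)", call. = FALSE)
  }
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    stop("`n` must be a count >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  pts <- withr::with_seed(seed, {
    g <- matrix(stats::rnorm(3L * n), ncol = 3L)
    u <- stats::runif(n)
    g / sqrt(rowSums(g^2)) * (r * u^(1 / 3))
  })
  colnames(pts) <- c("a", "b", "c")
  structure(list(points = pts, r = r, n = n, seed = as.integer(seed)),
            class = "sphere_points")
}

# squared distance of each point to each shifted sample, chunked over
# samples so the n_points x n_samples matrix never materializes whole;
# returns, per point, the count of samples with distance^2 <= thr2
.covered_counts <- function(points, xyz, thr2, chunk = 2000L) {
  p2 <- rowSums(points^2)
  counts <- numeric(nrow(points))
  n <- nrow(xyz)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    x <- xyz[idx, , drop = FALSE]
    # (p + x)^2 summed over axes = |p|^2 + |x|^2 + 2 p.x
    d2 <- outer(p2, rowSums(x^2), `+`) + 2 * points %*% t(x)
    counts <- counts + rowSums(d2 <= thr2)
  }
  counts
}

#' Monte Carlo dose-volume histogram of the lesion
#'
#' For every sampled point of the lesion and every recorded displacement
#' `(x, y, z)`, the point receives a unit of dose when it stays inside the
#' displaced boost sphere, i.e. when
#' `(a + x)^2 + (b + y)^2 + (c + z)^2 <= (r + m)^2`.  Each point's dose
#' fraction is its received units divided by the total number of
#' displacement samples; the cumulative curve gives, for each dose level,
#' the fraction of lesion volume receiving at least that dose.
#'
#' @param points A [sample_sphere()] point set; its radius must equal the
#'   lesion radius of `geom`.
#' @param trajectories A trajectory set ([as_trajectory_set()]).
#' @param geom A [sphere_geometry()].
#' @return An object of class `dvh_curve`: list with `dose` (per-point dose
#'   fractions in \[0, 1\]), `r`, `m`, `n_points`, `n_samples`.
#' @examples
#' ts <- simulate_cohort(motion_model_params(n_patients = 1,
#'                                           fractions_per_patient = 2))
#' curve <- compute_dvh(sample_sphere(5, 500, seed = 1), ts,
#'                      sphere_geometry(5, 2))
#' dvh_query_V(curve, 0.95)
#' @export
compute_dvh <- function(points, trajectories, geom) {
  stopifnot(inherits(points, "sphere_points"),
            inherits(geom, "sphere_geometry"))
  trajectories <- as_trajectory_set(trajectories)
  if (!isTRUE(all.equal(points$r, geom$r))) {
    stop("point set was sampled for radius ", points$r,
         " mm but the geometry has r = ", geom$r, " mm", call. = FALSE)
  }
  xyz <- cbind(trajectories$lat_mm, trajectories$long_mm,
               trajectories$vert_mm)
  counts <- .covered_counts(points$points, xyz, (geom$r + geom$m)^2)
  structure(
    list(dose = counts / nrow(xyz), r = geom$r, m = geom$m,
         n_points = points$n, n_samples = nrow(xyz)),
    class = "dvh_curve"
  )
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf(
    "<dvh_curve> r = %g mm, m = %g mm; %d points x %d samples; mean dose %.3f\n",
    x$r, x$m, x$n_points, x$n_samples, mean(x$dose)))
  invisible(x)
}

#' Dose at volume: D_V
#'
#' The largest dose fraction `D` such that at least `volume_fraction` of
#' the lesion volume receives dose >= `D`.  Computed as the lower order
#' statistic (the `ceiling(v * n)`-th largest per-point dose), a
#' conservative rule that guarantees the stated volume actually reaches the
#' reported dose.
#'
#' @param curve A [compute_dvh()] result.
#' @param volume_fraction Volume fraction in (0, 1\]; e.g. 0.8 queries the
#'   dose received by 80 percent of the lesion.
#' @return A dose fraction in \[0, 1\].
#' @export
dvh_query_D <- function(curve, volume_fraction) {
  stopifnot(inherits(curve, "dvh_curve"))
  if (!is.numeric(volume_fraction) || length(volume_fraction) != 1L ||
      is.na(volume_fraction) || volume_fraction <= 0 ||
      volume_fraction > 1) {
    stop("`volume_fraction` must be in (0, 1]", call. = FALSE)
  }
  s <- sort(curve$dose, decreasing = TRUE)
  n <- length(s)
  k <- ceiling(volume_fraction * n - 1e-9)
  s[min(max(k, 1L), n)]
}

#' Volume at dose: V_D
#'
#' The fraction of lesion volume receiving at least `dose_fraction` of the
#' nominal boost dose.
#'
#' @param curve A [compute_dvh()] result.
#' @param dose_fraction Dose fraction in \[0, 1\].
#' @return A volume fraction in \[0, 1\].
#' @export
dvh_query_V <- function(curve, dose_fraction) {
  stopifnot(inherits(curve, "dvh_curve"))
  if (!is.numeric(dose_fraction) || length(dose_fraction) != 1L ||
      is.na(dose_fraction) || dose_fraction < 0 || dose_fraction > 1) {
    stop("`dose_fraction` must be in [0, 1]", call. = FALSE)
  }
  mean(curve$dose >= dose_fraction)
}

#' Gridded DVH curve for reports
#'
#' Presentation-only 1-percent-step grid of the cumulative curve; the curve
#' itself is built from exact per-point dose values without binning.
#'
#' @param curve A [compute_dvh()] result.
#' @param step Dose grid step as a fraction (default 0.01).
#' @return A tibble with columns `dose_percent`, `volume_percent`.
#' @export
dvh_curve_table <- function(curve, step = 0.01) {
  stopifnot(inherits(curve, "dvh_curve"))
  dose <- seq(0, 1, by = step)
  tibble::tibble(
    dose_percent = 100 * dose,
    volume_percent = 100 * vapply(dose, function(D) mean(curve$dose >= D),
                                  numeric(1))
  )
}

#' Per-patient dose-volume histograms
#'
#' One DVH per patient and geometry, each using only that patient's pooled
#' displacement samples.  The same point set (per radius) is used for every
#' patient so that curves are directly comparable.
#'
#' @param trajectories A trajectory set ([as_trajectory_set()]).
#' @param radii Lesion radii in mm.
#' @param margins Safety margins in mm.
#' @param n Points per lesion sphere (default 5000).
#' @param seed RNG seed for the point sets.
#' @param patients Patients to include (default: all in the set); unknown
#'   ids are an error.
#' @return A tibble with columns `patient_id`, `r_mm`, `margin_mm` and a
#'   list-column `curve` of `dvh_curve` objects.
#' @export
dvh_per_patient <- function(trajectories, radii = c(3, 5, 7),
                            margins = c(0, 2, 5), n = 5000, seed = 1L,
                            patients = NULL) {
  trajectories <- as_trajectory_set(trajectories)
  .check_geometry_grid(radii, margins)
  all_patients <- unique(trajectories$patient_id)
  if (is.null(patients)) {
    patients <- all_patients
  } else {
    unknown <- setdiff(patients, all_patients)
    if (length(unknown) > 0L) {
      stop("unknown patient id(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  out <- list()
  for (r_i in seq_along(radii)) {
    pts <- sample_sphere(radii[r_i], n = n,
                         seed = derive_stream_seed(seed, r_i, 0L))
    for (m in margins) {
      geom <- sphere_geometry(radii[r_i], m)
      for (pid in patients) {
        sub <- trajectories[trajectories$patient_id == pid, ]
        out[[length(out) + 1L]] <- tibble::tibble(
          patient_id = pid, r_mm = radii[r_i], margin_mm = m,
          curve = list(compute_dvh(pts, sub, geom))
        )
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Plot one or more DVH curves
#'
#' Cumulative dose-volume curves, dose in percent of the nominal boost dose
#' on the horizontal axis and volume in percent of lesion volume on the
#' vertical axis.
#'
#' @param curves A named list of `dvh_curve` objects (names become the
#'   legend) or a single `dvh_curve`.
#' @param step Dose grid step for plotting (fraction).
#' @return A ggplot object.
#' @export
plot_dvh <- function(curves, step = 0.01) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_dvh() requires the ggplot2 package", call. = FALSE)
  }
  if (inherits(curves, "dvh_curve")) curves <- list(DVH = curves)
  df <- dplyr::bind_rows(lapply(curves, dvh_curve_table, step = step),
                         .id = "curve")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dose_percent,
                                   y = .data$volume_percent,
                                   colour = .data$curve)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::labs(x = "Dose (% of nominal boost dose)",
                  y = "Volume (% of lesion volume)", colour = NULL) +
    ggplot2::coord_cartesian(xlim = c(0, 100), ylim = c(0, 100))
}
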