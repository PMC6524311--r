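# Builders and independent oracles shared across tests.

# hand-built trajectory set; displacements as given, one sample per row
make_traj <- function(lat, long, vert, t = (seq_along(lat) - 1) * 5,
                      patient = "P01", fraction = "F01") {
  tibble::tibble(
    patient_id = patient, fraction_id = fraction, t_seconds = t,
    lat_mm = lat, long_mm = long, vert_mm = vert
  )
}

# trajectory set whose pooled radial distances are exactly `d` (along the
# lateral axis), for driving the coverage and DVH engines with known inputs
traj_with_distances <- function(d) {
  make_traj(lat = d, long = rep(0, length(d)), vert = rep(0, length(d)),
            t = (seq_along(d) - 1) * 5)
}

# independent Monte Carlo oracle for the lesion coverage fraction:
# rejection-sampled uniform points in the IPL ball (no package code), then
# the inclusion test against the boost sphere displaced by d along one axis
mc_ball_points <- function(n, r) {
  pts <- matrix(numeric(0), ncol = 3)
  while (nrow(pts) < n) {
    cand <- matrix(stats::runif(3 * ceiling(1.2 * n / 0.52), -r, r),
                   ncol = 3)
    cand <- cand[rowSums(cand^2) <= r^2, , drop = FALSE]
    pts <- rbind(pts, cand)
  }
  pts[seq_len(n), , drop = FALSE]
}

mc_coverage_ipl <- function(pts, r, m, d) {
  mean(pts[, 1]^2 + pts[, 2]^2 + (pts[, 3] - d)^2 <= (r + m)^2)
}

# small fast cohort for integration-style tests
small_cohort_params <- function(n_patients = 3, fractions_per_patient = 2,
                                seed = 42L, ...) {
  motion_model_params(n_patients = n_patients,
                      fractions_per_patient = fractions_per_patient,
                      seed = seed, ...)
}
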