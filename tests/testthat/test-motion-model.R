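test_that("parameter validation rejects non-physical configurations", {
  expect_error(motion_model_params(sigma_lat = -1), "sigma_lat")
  expect_error(motion_model_params(fraction_duration = 0), "positive")
  expect_error(motion_model_params(sample_interval = -5), "positive")
  expect_error(motion_model_params(n_patients = 0), ">= 1")
  expect_error(motion_model_params(patient_motility_sd = -0.1),
               "non-negative")
  expect_error(simulate_fraction(motion_model_params(),
                                 patient_multiplier = 0), "positive")
})

test_that("every fraction starts anchored at zero displacement", {
  p <- motion_model_params()
  for (seed in 1:5) {
    trj <- simulate_fraction(p, seed = seed)
    expect_identical(trj$t_seconds[1], 0)
    expect_identical(c(trj$lat_mm[1], trj$long_mm[1], trj$vert_mm[1]),
                     c(0, 0, 0))
  }
  # a fraction too short for a second sample is the anchor alone
  short <- motion_model_params(fraction_duration = 0.05,
                               sample_interval = 5)
  trj <- simulate_fraction(short, seed = 1)
  expect_equal(nrow(trj), 1L)
  expect_identical(unlist(trj), c(t_seconds = 0, lat_mm = 0, long_mm = 0,
                                  vert_mm = 0))
})

test_that("samples are spaced by the configured interval", {
  p <- motion_model_params(fraction_duration = 1, sample_interval = 10)
  trj <- simulate_fraction(p, seed = 7)
  expect_equal(trj$t_seconds, seq(0, 60, by = 10))
})

test_that("trajectories are deterministic in the seed, byte for byte", {
  p <- small_cohort_params()
  expect_identical(simulate_fraction(p, seed = 3),
                   simulate_fraction(p, seed = 3))
  a <- simulate_cohort(p)
  b <- simulate_cohort(p)
  expect_identical(a, b)
  fa <- withr::local_tempfile(fileext = ".csv")
  fb <- withr::local_tempfile(fileext = ".csv")
  write_trajectories(a, fa)
  write_trajectories(b, fb)
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fb, "raw", file.size(fb)))
})

test_that("simulating a fraction leaves the global RNG state alone", {
  p <- motion_model_params()
  withr::local_seed(99)
  before <- stats::runif(1)
  withr::local_seed(99)
  invisible(simulate_fraction(p, seed = 5))
  after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("pure drift with zero diffusion moves linearly in time", {
  p <- motion_model_params(sigma_lat = 0, sigma_long = 0, sigma_vert = 0,
                           drift_lat = 0.5, drift_long = -1,
                           drift_vert = 2,
                           fraction_duration = 2, sample_interval = 30)
  trj <- simulate_fraction(p, seed = 1)
  t_min <- trj$t_seconds / 60
  expect_equal(trj$lat_mm, 0.5 * t_min)
  expect_equal(trj$long_mm, -1 * t_min)
  expect_equal(trj$vert_mm, 2 * t_min)
})

test_that("displacement variance matches sigma^2 * t within Monte Carlo error", {
  # 10,000 replicate fractions of a unit-diffusion vertical axis: the
  # sample variance at t = 4 min estimates 4 mm^2
  p <- motion_model_params(sigma_lat = 0, sigma_long = 0, sigma_vert = 1,
                           drift_lat = 0, drift_long = 0, drift_vert = 0,
                           fraction_duration = 4, sample_interval = 60)
  n_rep <- 10000
  finals <- vapply(seq_len(n_rep), function(i) {
    trj <- simulate_fraction(p, seed = i)
    trj$vert_mm[trj$t_seconds == 240]
  }, numeric(1))
  v <- stats::var(finals)
  se <- 4 * sqrt(2 / (n_rep - 1))  # SE of a variance estimate near 4
  expect_lt(abs(v - 4), 3 * se)
  expect_lt(abs(mean(finals)), 3 * 2 / sqrt(n_rep))
})

test_that("the motility multiplier scales the diffusion quadratically", {
  p <- motion_model_params(sigma_lat = 0, sigma_long = 0, sigma_vert = 1,
                           drift_lat = 0, drift_long = 0, drift_vert = 0,
                           fraction_duration = 4, sample_interval = 240)
  n_rep <- 10000
  finals <- vapply(seq_len(n_rep), function(i) {
    simulate_fraction(p, patient_multiplier = 2, seed = i)$vert_mm[2]
  }, numeric(1))
  expect_lt(abs(stats::var(finals) - 16), 3 * 16 * sqrt(2 / (n_rep - 1)))
})

test_that("cohort has the configured shape and reproducible sub-streams", {
  p <- small_cohort_params(n_patients = 4, fractions_per_patient = 3)
  ts <- simulate_cohort(p)
  counts <- dplyr::count(dplyr::distinct(ts, patient_id, fraction_id),
                         patient_id)
  expect_equal(nrow(counts), 4L)
  expect_true(all(counts$n == 3L))
  # one fraction regenerated in isolation matches its slice of the cohort
  mult <- patient_motility_multiplier(p, 3)
  lone <- simulate_fraction(p, patient_multiplier = mult,
                            seed = derive_stream_seed(p$seed, 3, 2))
  slice <- ts[ts$patient_id == "P03" & ts$fraction_id == "F02",
              c("t_seconds", "lat_mm", "long_mm", "vert_mm")]
  expect_equal(as.data.frame(slice), as.data.frame(lone))
})

test_that("default cohort shape matches the tracked cohort", {
  p <- motion_model_params()
  n_fractions <- p$n_patients * p$fractions_per_patient
  expect_equal(p$n_patients, 28L)
  expect_lte(abs(n_fractions - 720L), p$n_patients)
})

test_that("zero motility spread makes all patients identical", {
  p <- small_cohort_params(patient_motility_sd = 0)
  for (pt in 1:3) expect_identical(patient_motility_multiplier(p, pt), 1)
})

test_that("motility spread separates low and high movers", {
  p <- motion_model_params(patient_motility_sd = 0.6, n_patients = 40,
                           fractions_per_patient = 2, seed = 11L)
  mult <- vapply(1:40, function(i) patient_motility_multiplier(p, i),
                 numeric(1))
  expect_gt(max(mult) / min(mult), 5)
  # the spread carries through to realized per-patient mean displacement
  pm <- patient_motility_table(simulate_cohort(p))
  expect_gt(max(pm$mean_radial_mm) / min(pm$mean_radial_mm), 4)
})

test_that("trajectory set contract is enforced", {
  expect_error(as_trajectory_set(data.frame(x = 1)), "missing column")
  good <- make_traj(1, 1, 1)
  expect_s3_class(as_trajectory_set(good), "tbl_df")
  bad_t <- make_traj(c(0, 1), c(0, 1), c(0, 1), t = c(10, 5))
  expect_error(as_trajectory_set(bad_t), "non-decreasing")
  bad_na <- make_traj(c(0, NA), c(0, 1), c(0, 1))
  expect_error(as_trajectory_set(bad_na), "missing values")
  expect_error(as_trajectory_set(good[0, ]), "empty")
})

test_that("trajectory CSV round-trips exactly", {
  ts <- simulate_cohort(small_cohort_params())
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectories(ts, f)
  back <- read_trajectories(f)
  expect_equal(as.data.frame(back), as.data.frame(ts), tolerance = 1e-12)
})
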