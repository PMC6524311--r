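#' Parameters of the intrafraction motion model
#'
#' The prostate is modelled as drifting from its image-guided
#' start-of-fraction position by a Gaussian random walk with deterministic
#' drift (Brownian motion with drift), independently on three anatomical
#' axes: lateral (left-right), longitudinal (cranial-caudal) and vertical
#' (anterior-posterior).  Under this model the displacement variance on each
#' axis grows linearly in elapsed time, \eqn{Var[x(t)] = \sigma^2 t}, which
#' distinguishes intrafraction motion from the constant-variance Gaussian
#' setup errors of classical margin recipes.
#'
#' Between-patient differences in motility are captured by a per-patient
#' multiplier applied to all three diffusion scales.  Multipliers are drawn
#' log-normally with `meanlog = -patient_motility_sd^2` and
#' `sdlog = patient_motility_sd`, so that the mean squared multiplier is 1
#' and the pooled displacement variance of a large cohort is unchanged by
#' the between-patient spread.
#'
#' Default diffusion scales are calibrated so that the pooled per-axis
#' standard deviations of a default cohort approximate 0.76 / 1.15 / 1.64 mm
#' (lateral / longitudinal / vertical): a Brownian path of duration `T`
#' sampled uniformly in time has pooled displacement variance
#' \eqn{\sigma^2 T / 2}, hence `sigma = target_sd / sqrt(T / 2)` with
#' `T = 4.46` minutes.
#'
#' @param sigma_lat,sigma_long,sigma_vert Per-axis diffusion scales in
#'   mm per square-root minute.  Must be non-negative.
#' @param drift_lat,drift_long,drift_vert Per-axis deterministic drift rates
#'   in mm per minute.  Defaults reproduce the small nonzero per-axis mean
#'   displacements seen in pooled tracking statistics.
#' @param patient_motility_sd Log-scale spread of the per-patient motility
#'   multiplier (dimensionless, >= 0).  0 makes all patients identical.
#' @param fraction_duration Duration of one treatment fraction in minutes.
#' @param sample_interval Position sampling interval in seconds.
#' @param n_patients,fractions_per_patient Cohort shape (counts >= 1).
#' @param seed Root RNG seed (integer); per-patient and per-fraction streams
#'   are derived from it, see [derive_stream_seed()].
#'
#' @return An object of class `motion_model_params` (a named list).
#' @examples
#' p <- motion_model_params(n_patients = 2, fractions_per_patient = 3)
#' p$sigma_vert
#' @seealso [simulate_fraction()], [simulate_cohort()]
#' @export
motion_model_params <- function(sigma_lat = 0.509,
                                sigma_long = 0.770,
                                sigma_vert = 1.098,
                                drift_lat = 0,
                                drift_long = -0.058,
                                drift_vert = 0.049,
                                patient_motility_sd = 0.45,
                                fraction_duration = 4.46,
                                sample_interval = 5,
                                n_patients = 28,
                                fractions_per_patient = 26,
                                seed = 20190516L) {
  params <- list(
    sigma_lat = sigma_lat, sigma_long = sigma_long, sigma_vert = sigma_vert,
    drift_lat = drift_lat, drift_long = drift_long, drift_vert = drift_vert,
    patient_motility_sd = patient_motility_sd,
    fraction_duration = fraction_duration,
    sample_interval = sample_interval,
    n_patients = as.integer(n_patients),
    fractions_per_patient = as.integer(fractions_per_patient),
    seed = as.integer(seed)
  )
  class(params) <- "motion_model_params"
  validate_motion_model_params(params)
  params
}

validate_motion_model_params <- function(params) {
  stopifnot(inherits(params, "motion_model_params"))
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("sigma_lat", "sigma_long", "sigma_vert")) {
    if (!num1(params[[f]]) || params[[f]] < 0) {
      stop("`", f, "` must be a single non-negative number", call. = FALSE)
    }
  }
  for (f in c("drift_lat", "drift_long", "drift_vert")) {
    if (!num1(params[[f]])) {
      stop("`", f, "` must be a single finite number", call. = FALSE)
    }
  }
  if (!num1(params$patient_motility_sd) || params$patient_motility_sd < 0) {
    stop("`patient_motility_sd` must be a single non-negative number",
         call. = FALSE)
  }
  if (!num1(params$fraction_duration) || params$fraction_duration <= 0) {
    stop("`fraction_duration` must be positive (minutes)", call. = FALSE)
  }
  if (!num1(params$sample_interval) || params$sample_interval <= 0) {
    stop("`sample_interval` must be positive (seconds)", call. = FALSE)
  }
  if (is.na(params$n_patients) || params$n_patients < 1L) {
    stop("`n_patients` must be >= 1", call. = FALSE)
  }
  if (is.na(params$fractions_per_patient) ||
      params$fractions_per_patient < 1L) {
    stop("`fractions_per_patient` must be >= 1", call. = FALSE)
  }
  if (is.na(params$seed)) stop("`seed` must be an integer", call. = FALSE)
  invisible(params)
}

#' @export
print.motion_model_params <- function(x, ...) {
  cat("<motion_model_params>\n")
  cat(sprintf("  diffusion (mm/sqrt-min): lat %.3f  long %.3f  vert %.3f\n",
              x$sigma_lat, x$sigma_long, x$sigma_vert))
  cat(sprintf("  drift (mm/min):          lat %.3f  long %.3f  vert %.3f\n",
              x$drift_lat, x$drift_long, x$drift_vert))
  cat(sprintf("  patient motility sdlog:  %.2f\n", x$patient_motility_sd))
  cat(sprintf("  fraction: %.2f min sampled every %g s\n",
              x$fraction_duration, x$sample_interval))
  cat(sprintf("  cohort: %d patients x %d fractions, seed %d\n",
              x$n_patients, x$fractions_per_patient, x$seed))
  invisible(x)
}

#' Derive a reproducible sub-stream seed
#'
#' Maps the root seed plus a (patient, fraction) counter pair onto a seed
#' below 2^31, so any patient's motility draw (`fraction = 0`) or any single
#' fraction (`fraction >= 1`) can be regenerated in isolation without
#' simulating the rest of the cohort.
#'
#' @param seed Root seed (integer).
#' @param patient Patient index, 1-based.
#' @param fraction Fraction index, 1-based; 0 addresses the patient-level
#'   motility stream.
#' @return An integer seed.
#' @export
derive_stream_seed <- function(seed, patient, fraction = 0L) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(patient) +
                2003 * as.numeric(fraction)) %% 2147483647)
}

#' Simulate one fraction of intrafraction prostate motion
#'
#' Generates a single treatment fraction's displacement trajectory relative
#' to the start-of-fraction position.  The first sample, at elapsed time 0,
#' is exactly (0, 0, 0); each subsequent sample adds an independent Gaussian
#' increment with per-axis standard deviation
#' `sigma_axis * sqrt(dt) * patient_multiplier` and mean `drift_axis * dt`,
#' `dt` in minutes, so the displacement variance grows linearly in elapsed
#' time.
#'
#' @param params A [motion_model_params()] object.
#' @param patient_multiplier Positive motility multiplier scaling the
#'   diffusion (not the drift) for this patient.
#' @param seed RNG seed for this fraction; the global RNG state is left
#'   untouched.
#' @return A tibble with columns `t_seconds`, `lat_mm`, `long_mm`,
#'   `vert_mm`, one row per sample, ordered in time.
#' @examples
#' p <- motion_model_params()
#' trj <- simulate_fraction(p, patient_multiplier = 1, seed = 1)
#' head(trj)
#' @export
simulate_fraction <- function(params, patient_multiplier = 1,
                              seed = params$seed) {
  validate_motion_model_params(params)
  if (!is.numeric(patient_multiplier) || length(patient_multiplier) != 1L ||
      !is.finite(patient_multiplier) || patient_multiplier <= 0) {
    stop("`patient_multiplier` must be a single positive number",
         call. = FALSE)
  }
  n_steps <- floor(params$fraction_duration * 60 / params$sample_interval)
  dt_min <- params$sample_interval / 60
  sd_ax <- c(params$sigma_lat, params$sigma_long, params$sigma_vert) *
    sqrt(dt_min) * patient_multiplier
  drift_ax <- c(params$drift_lat, params$drift_long, params$drift_vert) *
    dt_min
  if (n_steps == 0L) {
    return(tibble::tibble(t_seconds = 0, lat_mm = 0, long_mm = 0,
                          vert_mm = 0))
  }
  inc <- withr::with_seed(seed, {
    matrix(stats::rnorm(3L * n_steps), nrow = n_steps, ncol = 3L)
  })
  inc <- sweep(inc, 2L, sd_ax, `*`)
  inc <- sweep(inc, 2L, drift_ax, `+`)
  pos <- apply(inc, 2L, cumsum)
  pos <- matrix(pos, ncol = 3L)  # n_steps == 1 drops dims otherwise
  tibble::tibble(
    t_seconds = (0:n_steps) * params$sample_interval,
    lat_mm = c(0, pos[, 1L]),
    long_mm = c(0, pos[, 2L]),
    vert_mm = c(0, pos[, 3L])
  )
}

#' Simulate a full cohort of tracked fractions
#'
#' Generates `n_patients` patients with `fractions_per_patient` fractions
#' each.  Every patient receives one motility multiplier, drawn log-normally
#' (`meanlog = -patient_motility_sd^2`, `sdlog = patient_motility_sd`) from
#' a patient-specific derived seed, and keeps it for all their fractions.
#' Fractions are generated by [simulate_fraction()] under per-fraction
#' derived seeds, so any subset of the cohort is reproducible in isolation.
#'
#' @param params A [motion_model_params()] object.
#' @return A trajectory set: a tibble with columns `patient_id`,
#'   `fraction_id`, `t_seconds`, `lat_mm`, `long_mm`, `vert_mm` (see
#'   [as_trajectory_set()]).
#' @examples
#' ts <- simulate_cohort(motion_model_params(n_patients = 2,
#'                                           fractions_per_patient = 2))
#' dplyr::count(ts, patient_id, fraction_id)
#' @export
simulate_cohort <- function(params) {
  validate_motion_model_params(params)
  pid_fmt <- paste0("P%0", max(2L, nchar(params$n_patients)), "d")
  fid_fmt <- paste0("F%0", max(2L, nchar(params$fractions_per_patient)), "d")
  out <- vector("list", params$n_patients * params$fractions_per_patient)
  k <- 0L
  for (p in seq_len(params$n_patients)) {
    mult <- patient_motility_multiplier(params, p)
    for (f in seq_len(params$fractions_per_patient)) {
      trj <- simulate_fraction(params, patient_multiplier = mult,
                               seed = derive_stream_seed(params$seed, p, f))
      k <- k + 1L
      out[[k]] <- tibble::tibble(
        patient_id = sprintf(pid_fmt, p),
        fraction_id = sprintf(fid_fmt, f),
        trj
      )
    }
  }
  as_trajectory_set(dplyr::bind_rows(out))
}

#' Per-patient motility multiplier
#'
#' The log-normal motility multiplier assigned to one patient of the cohort
#' defined by `params`; deterministic given the root seed.
#'
#' @inheritParams simulate_cohort
#' @param patient Patient index, 1-based.
#' @return A single positive number; exactly 1 when
#'   `patient_motility_sd = 0`.
#' @export
patient_motility_multiplier <- function(params, patient) {
  validate_motion_model_params(params)
  s <- params$patient_motility_sd
  if (s == 0) return(1)
  withr::with_seed(derive_stream_seed(params$seed, patient, 0L),
                   stats::rlnorm(1L, meanlog = -s^2, sdlog = s))
}
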