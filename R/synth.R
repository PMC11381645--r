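#' Configuration of the synthetic CGM cohort generator
#'
#' A phenomenological type 1 diabetes trace model: a mean-reverting
#' stochastic baseline (Ornstein-Uhlenbeck with Euler steps on the
#' sampling grid) plus superimposed meal excursions (linear 30-minute
#' rise, then exponential decay) and hypoglycemic dips (Gaussian-shaped
#' drops towards an absolute nadir level), clamped to the sensor
#' reporting range, with slot dropout and multi-slot gaps applied last.
#' Scalar fields drive [simulate_patient()]; the `*_range` fields are
#' per-patient uniform draw ranges used by [simulate_cohort()] to grade
#' glycemic quality across the cohort.
#'
#' @param n_patients cohort size.
#' @param days_per_patient days of data per patient.
#' @param sample_interval_min sensor sampling interval, minutes.
#' @param basal_mean baseline glucose the process reverts to, mg/dL.
#' @param basal_mean_range cohort draw range for `basal_mean`.
#' @param reversion_rate mean-reversion rate, per hour.
#' @param diffusion_sd diffusion scale, mg/dL per sqrt(hour).
#' @param diffusion_sd_range cohort draw range for `diffusion_sd`.
#' @param meal_rate meal excursions per day (Poisson).
#' @param meal_amplitude median excursion amplitude, mg/dL (log-normal
#'   with 30% coefficient of variation).
#' @param meal_amplitude_range cohort draw range for `meal_amplitude`.
#' @param meal_halflife_h exponential decay half-life of an excursion,
#'   hours.
#' @param hypo_rate hypoglycemic dips per day (Poisson).
#' @param hypo_rate_range cohort draw range for `hypo_rate`.
#' @param hypo_nadir,hypo_nadir_sd mean and SD of the absolute glucose
#'   level a dip reaches, mg/dL.
#' @param hypo_duration_min full width of a dip, minutes.
#' @param dropout_prob per-slot independent dropout probability.
#' @param gap_rate sensor gaps per day (Poisson).
#' @param gap_mean_slots mean gap length in slots (geometric).
#' @param cohort_mix fraction of pediatric patients.
#' @param seed root seed; all randomness derives from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 50L, days_per_patient = 30L,
                       sample_interval_min = 15L,
                       basal_mean = 150, basal_mean_range = c(110, 220),
                       reversion_rate = 0.5,
                       diffusion_sd = 20, diffusion_sd_range = c(5, 22),
                       meal_rate = 3, meal_amplitude = 80,
                       meal_amplitude_range = c(30, 120),
                       meal_halflife_h = 1.0,
                       hypo_rate = 1, hypo_rate_range = c(0.1, 4),
                       hypo_nadir = 55, hypo_nadir_sd = 8,
                       hypo_duration_min = 75,
                       dropout_prob = 0.02, gap_rate = 0.5,
                       gap_mean_slots = 4, cohort_mix = 0.38,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_patients >= 1, cfg$days_per_patient >= 1,
            cfg$sample_interval_min >= 1,
            cfg$basal_mean > 54, cfg$basal_mean < 300,
            cfg$meal_rate >= 0, cfg$hypo_rate >= 0,
            cfg$dropout_prob >= 0, cfg$dropout_prob < 1,
            cfg$cohort_mix >= 0, cfg$cohort_mix <= 1)
  structure(cfg, class = "sim_config")
}

#' Simulate one patient's CGM series
#'
#' Deterministic given `(config$seed, patient_index)`: the same pair
#' always yields the identical series, independent of the caller's RNG
#' state.
#'
#' @param config a [sim_config()].
#' @param patient_index positive integer identifying the patient.
#' @param cohort `"adult"` or `"pediatric"`.
#' @return a `cgm_series` in mg/dL.
#' @examples
#' s <- simulate_patient(sim_config(days_per_patient = 5, seed = 3), 1)
#' s
#' @export
simulate_patient <- function(config, patient_index, cohort = "adult") {
  stopifnot(inherits(config, "sim_config"))
  interval <- config$sample_interval_min
  n <- as.integer(config$days_per_patient * 1440 / interval)
  dt <- interval / 60                       # hours per step
  minutes <- (seq_len(n) - 1) * interval
  with_seed(derive_seed(config$seed, patient_index), {
    # mean-reverting baseline
    g <- numeric(n)
    g[1] <- config$basal_mean
    eps <- stats::rnorm(n - 1, 0, config$diffusion_sd * sqrt(dt))
    for (t in seq_len(n - 1))
      g[t + 1] <- g[t] + config$reversion_rate *
        (config$basal_mean - g[t]) * dt + eps[t]
    # meal excursions: 30-min linear rise, exponential decay
    n_meals <- stats::rpois(1, config$meal_rate * config$days_per_patient)
    if (n_meals > 0) {
      m_time <- stats::runif(n_meals, 0, max(minutes))
      m_amp <- stats::rlnorm(n_meals, log(config$meal_amplitude), 0.3)
      half_min <- config$meal_halflife_h * 60
      for (j in seq_len(n_meals)) {
        rel <- minutes - m_time[j]
        eff <- ifelse(rel < 0, 0,
                      ifelse(rel < 30, m_amp[j] * rel / 30,
                             m_amp[j] * 2^(-(rel - 30) / half_min)))
        g <- g + eff
      }
    }
    # hypoglycemic dips towards an absolute nadir
    n_hypo <- stats::rpois(1, config$hypo_rate * config$days_per_patient)
    if (n_hypo > 0) {
      h_time <- stats::runif(n_hypo, 0, max(minutes))
      h_nadir <- stats::rnorm(n_hypo, config$hypo_nadir,
                              config$hypo_nadir_sd)
      kernel_sd <- config$hypo_duration_min / 2.355   # FWHM -> sd
      for (j in seq_len(n_hypo)) {
        at <- which.min(abs(minutes - h_time[j]))
        depth <- g[at] - h_nadir[j]
        if (depth <= 0) next
        g <- g - depth * exp(-((minutes - h_time[j])^2) /
                               (2 * kernel_sd^2))
      }
    }
    g <- pmin(pmax(g, SENSOR_RANGE[1]), SENSOR_RANGE[2])
    # missingness: independent dropout plus multi-slot gaps
    miss <- stats::runif(n) < config$dropout_prob
    n_gaps <- stats::rpois(1, config$gap_rate * config$days_per_patient)
    if (n_gaps > 0) {
      g_start <- sample.int(n, n_gaps, replace = TRUE)
      g_len <- 1 + stats::rgeom(n_gaps, 1 / config$gap_mean_slots)
      for (j in seq_len(n_gaps))
        miss[seq(g_start[j], min(n, g_start[j] + g_len[j] - 1))] <- TRUE
    }
    time <- as.POSIXct("2023-01-01 00:00:00", tz = "UTC") + minutes * 60
    new_cgm_series(time[!miss], g[!miss], "mg/dL",
                   sprintf("P%03d", patient_index), cohort)
  })
}

#' Simulate a graded synthetic cohort
#'
#' Draws per-patient generative parameters uniformly from the config's
#' `*_range` fields so glycemic quality is graded across the cohort
#' (some patients near target, some with heavy hypoglycemia,
#' hyperglycemia or variability burden), then simulates each patient.
#' The generative truth table is returned for parameter-recovery tests.
#'
#' @param config a [sim_config()].
#' @return list of class `cgm_cohort`: `series` (list of `cgm_series`),
#'   `truth` (per-patient generative parameters), `config`.
#' @examples
#' co <- simulate_cohort(sim_config(n_patients = 4,
#'                                  days_per_patient = 10, seed = 2))
#' co$truth
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_patients
  truth <- with_seed(derive_seed(config$seed, 0), data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    cohort = ifelse(seq_len(n) <= round(config$cohort_mix * n),
                    "pediatric", "adult"),
    basal_mean = stats::runif(n, config$basal_mean_range[1],
                              config$basal_mean_range[2]),
    diffusion_sd = stats::runif(n, config$diffusion_sd_range[1],
                                config$diffusion_sd_range[2]),
    meal_amplitude = stats::runif(n, config$meal_amplitude_range[1],
                                  config$meal_amplitude_range[2]),
    hypo_rate = stats::runif(n, config$hypo_rate_range[1],
                             config$hypo_rate_range[2]),
    meal_rate = config$meal_rate))
  series <- lapply(seq_len(n), function(i) {
    cfg_i <- config
    cfg_i$basal_mean <- truth$basal_mean[i]
    cfg_i$diffusion_sd <- truth$diffusion_sd[i]
    cfg_i$meal_amplitude <- truth$meal_amplitude[i]
    cfg_i$hypo_rate <- truth$hypo_rate[i]
    simulate_patient(cfg_i, i, truth$cohort[i])
  })
  structure(list(series = series, truth = truth, config = config),
            class = "cgm_cohort")
}

#' @export
print.cgm_cohort <- function(x, ...) {
  cat(sprintf("Synthetic CGM cohort: %d patients x %d days (seed %d)\n",
              x$config$n_patients, x$config$days_per_patient,
              x$config$seed))
  cat(sprintf("  %d pediatric, %d adult\n",
              sum(x$truth$cohort == "pediatric"),
              sum(x$truth$cohort == "adult")))
  invisible(x)
}
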