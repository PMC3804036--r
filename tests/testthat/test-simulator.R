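test_that("contact-pressure response honours its contract", {
  cfg <- simulation_config()

  expect_identical(cp_from_sd(cfg, 0), 0)

  cfg2 <- simulation_config(stiffness_linear = 0, stiffness_quad = 8)
  expect_equal(cp_from_sd(cfg2, 2), 32)

  # strictly increasing on a grid spanning both regimes, continuous
  # across the blend point
  grid <- seq(0, 0.999 * cfg$occlusion_depth_mm, length.out = 400)
  cp <- cp_from_sd(cfg, grid)
  expect_true(all(diff(cp) > 0))
  s0 <- 0.9 * cfg$occlusion_depth_mm
  eps <- 1e-7
  expect_equal(cp_from_sd(cfg, s0 + eps), cp_from_sd(cfg, s0 - eps),
               tolerance = 1e-4)

  expect_error(cp_from_sd(cfg, cfg$occlusion_depth_mm), "diverges")
  expect_error(cp_from_sd(cfg, -1), ">= 0")
})

test_that("sd_from_cp inverts cp_from_sd to the stated tolerance", {
  cfg <- simulation_config()
  targets <- c(5, 40, 110, 180, 300)
  sd <- sd_from_cp(cfg, targets)
  expect_equal(cp_from_sd(cfg, sd), targets, tolerance = 1e-3)
  expect_true(all(abs(sd - vapply(targets, function(p) {
    uniroot(function(s) cp_from_sd(cfg, s) - p,
            c(0, cfg$occlusion_depth_mm - 1e-9), tol = 1e-10)$root
  }, numeric(1))) < 1e-5))
  expect_error(sd_from_cp(cfg, 1e9), "not attainable")
})

test_that("amplitude envelope is a Gaussian bell with argmax at the optimal depth", {
  cfg <- simulation_config()
  d <- cfg$optimal_depth_mm
  w <- cfg$envelope_width_mm
  expect_equal(amplitude_at_sd(cfg, d), cfg$peak_amplitude_mmHg)
  expect_equal(amplitude_at_sd(cfg, d + w), amplitude_at_sd(cfg, d - w))
  expect_equal(amplitude_at_sd(cfg, d + w),
               cfg$peak_amplitude_mmHg * exp(-0.5))
  grid <- seq(0, 7, by = 1e-3)
  expect_equal(grid[which.max(amplitude_at_sd(cfg, grid))], d,
               tolerance = 1e-3)
})

test_that("CETM simulation matches its sampling, beat-count and determinism contracts", {
  cfg <- simulation_config(duration_s = 60, contact_time_s = 3,
                           optimal_depth_mm = 2.5, seed = 7)
  sim <- suppressWarnings(simulate_cetm(cfg))
  expect_identical(length(sim$recording$pressure_mmHg), 12000L)

  # 75 bpm over a 48 s post-contact span: 60 onsets (within 1)
  cfg2 <- simulation_config(duration_s = 51, contact_time_s = 3,
                            optimal_depth_mm = 2.2, heart_rate_bpm = 75)
  sim2 <- suppressWarnings(simulate_cetm(cfg2))
  expect_lte(abs(length(sim2$truth$true_onset_times_s) - 60), 1)

  sim_b <- suppressWarnings(simulate_cetm(cfg))
  expect_identical(sim$recording$pressure_mmHg, sim_b$recording$pressure_mmHg)

  # truncated-envelope warning contract
  expect_warning(simulate_cetm(simulation_config(duration_s = 30)),
                 "truncated")
  expect_error(simulate_cetm(simulation_config(duration_s = 200)),
               "occlusion")
})

test_that("noiseless CETM per-beat amplitudes reproduce the generator envelope", {
  sim <- noiseless_sim()
  fit <- noiseless_fit()
  cfg <- sim$truth$config
  env <- fit$envelope
  # peak minus foot samples the envelope at the systolic peak's
  # displacement
  post <- fit$beats$onset_time_s >= fit$contact$contact_time_s
  sd_peak <- cfg$velocity_mm_s *
    (fit$beats$peak_time_s[post] - cfg$contact_time_s)
  truth <- amplitude_at_sd(cfg, pmax(0, sd_peak))
  mid <- truth > 2  # leave out the tiny tail beats
  expect_lt(max(abs(env$amplitude_mmHg[mid] - truth[mid]) / truth[mid]), 0.02)
  expect_gt(correlation_r2(env$amplitude_mmHg, truth), 0.99)
})

test_that("stepwise simulation hits its arithmetic and envelope contracts", {
  cfg <- simulation_config(noise_sd_mmHg = 0, wander_amp_mmHg = 0, seed = 5)
  sim <- simulate_stepwise(cfg)
  # 3 s lead-in + 5 steps x 5 s at 200 Hz
  expect_identical(length(sim$recording$pressure_mmHg), as.integer(28 * 200))

  # the step nearest CP(optimal depth) carries the largest amplitude
  cp_opt <- cp_from_sd(cfg, cfg$optimal_depth_mm)
  steps <- sim$recording$meta$step_pressures_mmHg
  expect_identical(which.max(sim$truth$true_step_amplitudes_mmHg),
                   which.min(abs(steps - cp_opt)))

  # zero noise / zero wander: measured per-step amplitude equals the
  # envelope at the inverted step displacement
  fit <- quiet_assess(sim$recording)
  expect_equal(fit$envelope$amplitude_mmHg,
               sim$truth$true_step_amplitudes_mmHg, tolerance = 0.02)

  expect_error(simulate_stepwise(cfg, step_pressures_mmHg = c(40, 20)),
               "strictly increasing")
  expect_error(simulate_stepwise(cfg, step_pressures_mmHg = c(40, 1e8)),
               "not attainable")
})

test_that("cohort simulation is seeded, sized and converges to its location means", {
  coh <- simulate_cohort(n_subjects = 18, n_repeats = 2, seed = 3,
                         signals = FALSE)
  expect_identical(nrow(coh$truth_table), 108L)

  # zero jitter: both repeats of a subject identical
  coh0 <- simulate_cohort(n_subjects = 4, n_repeats = 2, seed = 3,
                          repeat_jitter_sd_mm = 0, signals = FALSE)
  tt <- coh0$truth_table
  sp <- split(tt$true_pdi_mm, interaction(tt$subject_id, tt$location))
  expect_true(all(vapply(sp, function(v) diff(range(v)) == 0, logical(1))))

  # law of large numbers on the per-location mean
  big <- simulate_cohort(n_subjects = 500, n_repeats = 1, seed = 9,
                         signals = FALSE)
  lp <- default_location_params()
  for (loc in names(lp)) {
    v <- big$truth_table$true_pdi_mm[big$truth_table$location == loc]
    se <- sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v) - lp[[loc]]$depth_mean_mm), 3 * se)
  }

  # determinism of the whole cohort draw
  coh_b <- simulate_cohort(n_subjects = 4, n_repeats = 2, seed = 3,
                           signals = FALSE)
  coh_c <- simulate_cohort(n_subjects = 4, n_repeats = 2, seed = 3,
                           signals = FALSE)
  expect_identical(coh_b$truth_table, coh_c$truth_table)
})
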