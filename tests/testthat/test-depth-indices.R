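test_that("contact detection finds the simulated contact time", {
  # noiseless: within 0.05 s of the true contact
  sim <- noiseless_sim()
  fs <- 200
  trend <- pulsedepth:::lowpass_filter(sim$recording$pressure_mmHg, fs, 0.3)
  ct <- detect_contact_point(sim$recording, trend)
  expect_equal(ct$contact_time_s, sim$truth$true_contact_time_s,
               tolerance = 0.05)
  expect_equal(ct$sd_contact_mm, 0.09 * ct$contact_time_s)

  # with default noise: bounded error over a small seeded batch; the
  # residual error is bounded by the slow initial pressure growth and
  # stays far below what matters for the depth index (0.1 mm ~ 1.1 s)
  errs <- vapply(1:8, function(s) {
    simn <- quiet_cetm(seed = 400 + s)
    tr <- pulsedepth:::lowpass_filter(simn$recording$pressure_mmHg, fs, 0.3)
    detect_contact_point(simn$recording, tr)$contact_time_s -
      simn$truth$true_contact_time_s
  }, numeric(1))
  expect_lt(median(abs(errs)), 1)
  expect_lt(max(abs(errs)), 2.5)

  # all-zero signal: no contact, informative error
  flat <- tonometry_recording(rep(0, 4000), fs, "cetm", velocity_mm_s = 0.09)
  tr0 <- rep(0, 4000)
  expect_error(detect_contact_point(flat, tr0), "contact")
})

test_that("envelope construction follows the protocol contracts", {
  sim <- noiseless_sim()
  fit <- noiseless_fit()
  env <- fit$envelope
  cfg <- sim$truth$config

  # argmax displacement within one beat spacing of the true optimum
  beat_sd <- cfg$velocity_mm_s * 60 / cfg$heart_rate_bpm
  sd_rel <- env$sd_mm[which.max(env$amplitude_mmHg)] -
    cfg$velocity_mm_s * cfg$contact_time_s
  expect_lt(abs(sd_rel - cfg$optimal_depth_mm), 1.5 * beat_sd)

  # CP non-decreasing along a noiseless CETM envelope
  expect_true(all(diff(env$cp_mmHg) > -0.5))

  # stepwise: one point per step
  sims <- simulate_stepwise(simulation_config(seed = 5))
  fits <- quiet_assess(sims$recording)
  expect_identical(nrow(fits$envelope), 5L)
})

test_that("OCP locates the envelope peak for both protocols", {
  # symmetric stepwise amplitudes force the interior centre
  env <- make_envelope(sd = rep(NA_real_, 5),
                       cp = c(40, 70, 110, 140, 180),
                       amp = c(1, 2, 5, 2, 1), protocol = "stepwise")
  r <- compute_ocp(env)
  expect_equal(r$ocp_mmHg, 110, tolerance = 0.1)
  expect_false(r$boundary)

  # monotone amplitudes: boundary flag at cp_max
  env2 <- make_envelope(rep(NA_real_, 5), c(40, 70, 110, 140, 180),
                        c(1, 2, 3, 4, 5), protocol = "stepwise")
  r2 <- compute_ocp(env2)
  expect_equal(r2$ocp_mmHg, 180)
  expect_true(r2$boundary)

  # noiseless CETM: OCP near the contact pressure at the true optimum
  sim <- noiseless_sim()
  fit <- noiseless_fit()
  cp_true <- cp_from_sd(sim$truth$config, sim$truth$config$optimal_depth_mm)
  expect_lt(abs(fit$indices$ocp_mmHg - cp_true), 3)

  # smoothed argmax equals a brute-force scan of the smoothed envelope
  sm <- pulsedepth:::smooth_envelope(fit$envelope$amplitude_mmHg, 5)
  i_brute <- which(sm == max(sm))[1]
  expect_identical(compute_ocp(fit$envelope)$argmax_index, i_brute)
})

test_that("CFS_ocp normalisation matches its closed form and bounds", {
  expect_identical(compute_cfs_ocp(40, 40, 180), 0)
  expect_identical(compute_cfs_ocp(180, 40, 180), 1)
  expect_identical(compute_cfs_ocp(110, 40, 180), 0.5)
  expect_error(compute_cfs_ocp(30, 40, 180), "outside")
  expect_error(compute_cfs_ocp(50, 60, 60), "below")
})

test_that("CFS_pad follows the amplitude-difference formula and stays in [0, 1]", {
  sector_cp <- c(70, 100, 130, 150, 180)  # one point per sector of [60, 195]

  env_eq <- make_envelope(1:5, sector_cp, c(2, 9, 9, 9, 2))
  expect_equal(compute_cfs_pad(env_eq)$cfs_pad, 0.5)

  env31 <- make_envelope(1:5, sector_cp, c(1, 9, 9, 9, 3))
  expect_equal(compute_cfs_pad(env31)$cfs_pad, 0.75)

  env_b <- make_envelope(1:5, sector_cp, c(0, 9, 9, 9, 3))
  expect_equal(compute_cfs_pad(env_b)$cfs_pad, 1)

  # property: random envelopes stay in [0, 1]
  set.seed(42)
  for (i in 1:50) {
    amp <- runif(20, 0, 30)
    cp <- sort(runif(20, 60, 195))
    v <- compute_cfs_pad(make_envelope(seq_len(20), cp, amp))$cfs_pad
    expect_gte(v, 0)
    expect_lte(v, 1)
  }

  # missing required sector and zero-amplitude errors are named
  env_gap <- make_envelope(1:3, c(70, 100, 130), c(1, 2, 3))
  expect_error(compute_cfs_pad(env_gap), "sector 5")
  env_zero <- make_envelope(1:5, sector_cp, c(0, 1, 1, 1, 0))
  expect_error(compute_cfs_pad(env_zero), "undefined|zero")

  # averaged-pairs mode uses sectors (1,5) and (2,4)
  env_p <- make_envelope(1:5, sector_cp, c(1, 1, 9, 3, 3))
  r <- compute_cfs_pad(env_p, pairs_mode = "averaged")
  expect_equal(r$cfs_pad, mean(c(3 / 4, 3 / 4)))
})

test_that("PDI is the displacement from contact to the envelope argmax", {
  # direct arithmetic on a hand-built envelope
  env <- make_envelope(sd = seq(2.4, 8.4, by = 0.5),
                       cp = seq(40, 160, by = 10),
                       amp = c(1, 2, 4, 7, 10, 9, 6, 4, 3, 2, 1.5, 1, 0.8))
  r <- compute_pdi(env, sd_contact_mm = 2.4)
  sm <- pulsedepth:::smooth_envelope(env$amplitude_mmHg, 5)
  expect_identical(r$sd_optimal_mm, env$sd_mm[which.max(sm)])
  expect_identical(r$pdi_mm, r$sd_optimal_mm - 2.4)

  # stepwise protocol refuses PDI
  envs <- make_envelope(rep(NA_real_, 5), c(40, 70, 110, 140, 180),
                        1:5, protocol = "stepwise")
  expect_error(compute_pdi(envs, 0), "CETM")

  # end-to-end noiseless recovery
  sim <- noiseless_sim()
  fit <- noiseless_fit()
  expect_lt(abs(fit$indices$pdi_mm - sim$truth$true_pdi_mm), 0.15)
})

test_that("assess_depth satisfies the index invariants and is deterministic", {
  fit <- quiet_assess(noisy_sim()$recording)
  ind <- fit$indices
  expect_gte(ind$cfs_ocp, 0); expect_lte(ind$cfs_ocp, 1)
  expect_gte(ind$cfs_pad, 0); expect_lte(ind$cfs_pad, 1)
  expect_gte(ind$pdi_mm, 0)
  expect_equal(ind$pdi_mm, ind$sd_optimal_mm - ind$sd_contact_mm)

  fit2 <- quiet_assess(noisy_sim()$recording)
  expect_identical(coef(fit), coef(fit2))

  # stepwise: CP indices present, PDI absent-by-protocol
  sims <- simulate_stepwise(simulation_config(seed = 6))
  fs_fit <- quiet_assess(sims$recording)
  expect_true(is.na(fs_fit$indices$pdi_mm))
  expect_false(is.na(fs_fit$indices$ocp_mmHg))
  expect_false(is.na(fs_fit$indices$cfs_pad))
})

test_that("raising the simulated optimal depth raises recovered PDI and never lowers OCP", {
  depths <- c(2.6, 3.4, 4.2, 5.0)
  res <- vapply(depths, function(d) {
    sim <- quiet_cetm(optimal_depth_mm = d, noise_sd_mmHg = 0,
                      wander_amp_mmHg = 0, seed = 55)
    co <- coef(quiet_assess(sim$recording))
    c(co[["pdi_mm"]], co[["ocp_mmHg"]])
  }, numeric(2))
  expect_true(all(diff(res[1, ]) > 0))
  expect_true(all(diff(res[2, ]) >= 0))
})
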