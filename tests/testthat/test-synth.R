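test_that("noise-free flight traces reproduce their generating parameters exactly", {
  sp <- species_profile("exact", endothermy_true = 5, noise_sd = 0)
  sim <- simulate_flight_trace(sp, trace_sim_config(seed = 1))
  expect_equal(compute_endothermy(sim$t_th, sim$t_env, sim$window), 5,
               tolerance = 1e-12)

  sp2 <- species_profile("drift", endothermy_true = 3,
                         slope_th_true = -0.003, noise_sd = 0)
  sim2 <- simulate_flight_trace(sp2, trace_sim_config(seed = 1))
  expect_equal(fit_slope(sim2$t_th, sim2$window), -0.003, tolerance = 1e-10)
  # mean excess still equals the planted endothermy despite the slope
  expect_equal(compute_endothermy(sim2$t_th, sim2$t_env, sim2$window), 3,
               tolerance = 1e-12)
})

test_that("noisy fitted slope stays within OLS standard error of the truth", {
  sp <- species_profile("noisy", endothermy_true = 4, slope_th_true = -0.003,
                        noise_sd = 0.3)
  cfg <- trace_sim_config(seed = 42)
  sim <- simulate_flight_trace(sp, cfg)
  tt <- sim$t_th$times[sim$t_th$times >= sim$window$takeoff_time]
  se <- 0.3 / sqrt(sum((tt - mean(tt))^2))
  expect_lt(abs(fit_slope(sim$t_th, sim$window) - (-0.003)), 4 * se)
})

test_that("same seed gives bit-identical traces, different seed differs", {
  sp <- species_profile("det", endothermy_true = 4, noise_sd = 0.3)
  a <- simulate_flight_trace(sp, trace_sim_config(seed = 11))
  b <- simulate_flight_trace(sp, trace_sim_config(seed = 11))
  c <- simulate_flight_trace(sp, trace_sim_config(seed = 12))
  expect_identical(a$t_th$values, b$t_th$values)
  expect_identical(a$t_abd$values, b$t_abd$values)
  expect_false(identical(a$t_th$values, c$t_th$values))
})

test_that("invalid profiles and configs are rejected", {
  expect_error(species_profile("bad", mass_mean = -1), "mass_mean")
  expect_error(species_profile("bad", endothermy_true = NaN))
  expect_error(species_profile("bad", mechanism_true = "APHT",
                               slope_th_true = -0.01), "APHT")
  expect_error(trace_sim_config(duration = 30), ">= 40")
  expect_error(trace_sim_config(frame_rate = 0), "frame_rate")
})

test_that("frame stacks carry the traces as 3x3 patch maxima", {
  sp <- species_profile("st", endothermy_true = 5, noise_sd = 0)
  sim <- simulate_flight_trace(sp, trace_sim_config(seed = 3))
  st <- simulate_frame_stack(sim)
  k <- 200
  rois <- attr(st, "rois")
  thorax <- rois[rois$label == "thorax", ]
  patch <- st$frames[[k]][(thorax$center_row - 1):(thorax$center_row + 1),
                          (thorax$center_col - 1):(thorax$center_col + 1)]
  expect_equal(max(patch), sim$t_th$values[k])
  expect_true(all(patch <= sim$t_th$values[k]))

  # full round trip through the extractor at zero noise
  for (lab in c("thorax", "abdomen", "environment")) {
    rc <- rois[rois$label == lab, ]
    tr <- extract_roi_trace(st, rc$center_row, rc$center_col, lab)
    truth <- switch(lab, thorax = sim$t_th, abdomen = sim$t_abd,
                    environment = sim$t_env)
    expect_equal(tr$values, truth$values, tolerance = 1e-12)
  }
})

test_that("<=1 px patch jitter is absorbed by the 3x3 maximum at the nominal center", {
  sp <- species_profile("jit", endothermy_true = 5, noise_sd = 0)
  sim <- simulate_flight_trace(sp, trace_sim_config(seed = 4))
  st <- simulate_frame_stack(sim, jitter_px = 1, seed = 9)
  rois <- attr(st, "rois")
  th <- rois[rois$label == "thorax", ]
  tr <- extract_roi_trace(st, th$center_row, th$center_col, "thorax")
  expect_equal(tr$values, sim$t_th$values, tolerance = 1e-12)
})

test_that("overlapping or out-of-frame patches are rejected", {
  sp <- species_profile("ov", endothermy_true = 5, noise_sd = 0)
  sim <- simulate_flight_trace(sp, trace_sim_config(seed = 5))
  expect_error(simulate_frame_stack(sim, centers = list(thorax = c(8, 8),
                                                        abdomen = c(8, 10),
                                                        environment = c(24, 16))),
               "overlap")
  expect_error(simulate_frame_stack(sim, centers = list(thorax = c(1, 8),
                                                        abdomen = c(8, 24),
                                                        environment = c(24, 16))),
               "outside")
})

test_that("endothermy recovery error over 200 individuals beats 3 sd / sqrt(n)", {
  sp <- species_profile("rec", endothermy_true = 6, noise_sd = 0.3)
  errs <- vapply(seq_len(200), function(i) {
    sim <- simulate_flight_trace(sp, trace_sim_config(seed = 5000 + i))
    n_win <- sum(sim$t_th$times >= sim$window$takeoff_time)
    est <- compute_endothermy(sim$t_th, sim$t_env, sim$window)
    abs(est - sim$truth$endothermy_true)
  }, numeric(1))
  n_frames <- sum(simulate_flight_trace(sp, trace_sim_config(seed = 1)
                  )$t_th$times >= 5)
  expect_lt(mean(errs), 3 * 0.3 / sqrt(n_frames))
})

test_that("community simulation plants recoverable indicators and rejects degenerate configs", {
  pool <- c("ind_sp", "null_sp")
  cfg <- community_sim_config(pool, habitat_true = c("native_forest",
                                                     "agroforestry"),
                              mean_own = c(50, 10), mean_other = c(0, 10),
                              seed = 21)
  sim <- simulate_community(cfg)
  expect_true(all(sim$counts >= 0))
  expect_true(all(sim$counts == round(sim$counts)))
  expect_identical(dim(sim$counts), c(9L, 2L))
  expect_true(sim$truth$planted_indicator[1])
  expect_false(sim$truth$planted_indicator[2])
  expect_error(community_sim_config(character(0)), "at least one species")
  expect_error(community_sim_config("a", sites_per_habitat = 1), ">= 2")
})

test_that("capture simulation hits the configured diurnal fraction", {
  cfg <- capture_sim_config("sp", diurnal_fraction = 0.9,
                            total_captures = 100, seed = 31)
  sim <- simulate_captures(cfg)
  per <- bin_capture_periods(sim$captures$timestamp)
  frac <- mean(per == "P1")
  # binomial(100, 0.9): 4 sd band
  expect_lt(abs(frac - 0.9), 4 * sqrt(0.9 * 0.1 / 100))
  expect_identical(classify_activity(sum(per == "P1"), sum(per == "P2"))$call,
                   "diurnal")
  expect_error(capture_sim_config("sp", total_captures = 0), "positive")
  expect_error(capture_sim_config("sp", diurnal_fraction = 1.2), "0, 1")
})

test_that("sensor logs carry the planted diel cycle", {
  cfg <- sensor_sim_config(diel_mean = 24, diel_amplitude = 10.5,
                           noise_sd = 0, seed = 41)
  sim <- simulate_sensor_log(cfg)
  ds <- summarize_sensor_log(sim$log)
  expect_equal(ds$amplitude, 21, tolerance = 1e-12)
  expect_equal(ds$day_max, sim$truth$day_max_expected, tolerance = 1e-12)
  expect_equal(ds$night_min, sim$truth$night_min_expected, tolerance = 1e-12)
  expect_error(sensor_sim_config(interval_min = 7), "1440")
  expect_error(sensor_sim_config(days = 0), ">= 1")
})
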