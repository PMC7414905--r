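test_that("ROI extraction takes the 3x3 maximum and ignores outside pixels", {
  m <- matrix(0, 5, 5)
  m[1:3, 1:3] <- c(20, 23, 25, 21, 30, 26, 22, 24, 27)  # max 30
  m[5, 5] <- 99  # outside the ROI window
  st <- frame_stack(list(m), 0.04)
  expect_equal(extract_roi_trace(st, 2, 2)$values, 30)

  const <- frame_stack(list(matrix(25, 4, 4), matrix(25, 4, 4)), c(0, 0.04))
  expect_equal(extract_roi_trace(const, 2, 2)$values, c(25, 25))

  # invariance: perturbing pixels outside the window never changes the trace
  set.seed(1)
  for (i in 1:20) {
    m2 <- matrix(runif(49, 20, 30), 7, 7)
    base <- extract_roi_trace(frame_stack(list(m2), 1), 4, 4)$values
    m3 <- m2
    mask <- matrix(TRUE, 7, 7); mask[3:5, 3:5] <- FALSE
    m3[mask] <- m3[mask] + runif(sum(mask), -5, 5)
    expect_identical(extract_roi_trace(frame_stack(list(m3), 1), 4, 4)$values,
                     base)
  }
  expect_error(extract_roi_trace(st, 1, 2), "outside")
})

test_that("radiometric correction has the expected identity and fixed points", {
  tr <- make_linear_trace()
  # emissivity 1, transmittance 1: identity
  out <- correct_temperature(tr, radiometric_params(emissivity = 1))
  expect_equal(out$values, tr$values, tolerance = 1e-12)
  expect_true(out$corrected)
  # object indistinguishable from the reflection: correction is a no-op
  tr2 <- temp_trace(0:10, rep(30, 11))
  out2 <- correct_temperature(tr2, radiometric_params(emissivity = 0.95,
                                                      reflected_temp = 30))
  expect_equal(out2$values, tr2$values, tolerance = 1e-10)
  expect_error(correct_temperature(out, radiometric_params()),
               "already corrected")
})

test_that("correction matches a hand evaluation of the T^4 inversion", {
  # e = 0.9, apparent 40 C, reflected 20 C, tau = 1
  w <- function(tc) (tc + 273.15)^4
  expected <- ((w(40) - 0.1 * w(20)) / 0.9)^0.25 - 273.15
  tr <- temp_trace(0, 40)
  out <- correct_temperature(tr, radiometric_params(emissivity = 0.9,
                                                    reflected_temp = 20))
  expect_equal(out$values, expected, tolerance = 1e-12)
})

test_that("correction inverts the forward model for any emissivity", {
  set.seed(2)
  for (i in 1:25) {
    e <- runif(1, 0.05, 1)
    refl <- runif(1, 10, 30)
    truth <- runif(5, 20, 45)
    apparent <- apparent_oracle(truth, e, refl)
    out <- correct_temperature(temp_trace(1:5, apparent),
                               radiometric_params(emissivity = e,
                                                  reflected_temp = refl))
    expect_equal(out$values, truth, tolerance = 1e-9)
  }
})

test_that("emissivity estimation recovers the forward model", {
  # identical emitters: estimate equals the reference emissivity
  ref <- seq(50, 80, by = 5)
  expect_equal(estimate_emissivity(ref, ref, epsilon_ref = 0.95,
                                   reflected_temp = 25), 0.95,
               tolerance = 1e-12)
  # pairs generated at emissivity 0.85: recovery to >= 4 decimals
  truth <- seq(50, 80, by = 5)
  cut_app <- apparent_oracle(truth, 0.85, 25)
  ref_app <- apparent_oracle(truth, 0.95, 25)
  expect_equal(estimate_emissivity(cut_app, ref_app, 0.95, 25), 0.85,
               tolerance = 1e-5)
  expect_error(estimate_emissivity(50, 50), "at least 2")
  expect_error(estimate_emissivity(c(25, 25), c(25, 25), 0.95, 25),
               "zero-variance")
})

test_that("flight windows honor annotations, the 40-s rule and the take-off heuristic", {
  tr45 <- temp_trace(seq(0, 45, by = 0.5), rep(30, 91))
  w <- detect_flight_window(tr45, takeoff_time = 2)
  expect_equal(w$takeoff_time, 2)
  expect_equal(w$end_time, 45)
  expect_true(w$qualifies)

  tr30 <- temp_trace(seq(0, 30, by = 0.5), rep(30, 61))
  expect_false(detect_flight_window(tr30)$qualifies)

  # step warm-up at 5 s: detected take-off within one frame
  sp <- species_profile("step", endothermy_true = 6, warmup_amplitude = 2,
                        noise_sd = 0.05)
  sim <- simulate_flight_trace(sp, trace_sim_config(seed = 8))
  w2 <- detect_flight_window(sim$t_th)
  expect_lt(abs(w2$takeoff_time - 5), 1 / 25 + 1e-9)
})

test_that("qualifying windows never pass flights shorter than the minimum", {
  set.seed(3)
  for (i in 1:50) {
    len <- runif(1, 5, 90)
    n <- max(ceiling(len * 2), 3)
    tr <- temp_trace(seq(0, len, length.out = n), rnorm(n, 30, 0.2))
    w <- detect_flight_window(tr, takeoff_time = 0)
    expect_identical(w$qualifies, (w$end_time - w$takeoff_time) >= 40)
    if (w$qualifies) expect_gte(w$end_time - w$takeoff_time, 40)
  }
})

test_that("frame stacks survive a TIFF + sidecar round trip", {
  sp <- species_profile("io", endothermy_true = 5, noise_sd = 0.2)
  sim <- simulate_flight_trace(sp, trace_sim_config(seed = 12))
  st <- simulate_frame_stack(sim)
  st$frames <- st$frames[1:20]
  st$frame_times <- st$frame_times[1:20]
  path <- tempfile(fileext = ".tiff")
  on.exit(unlink(c(path, sub("\\.tiff$", "_times.csv", path))))
  write_frame_stack(st, path)
  back <- read_frame_stack(path)
  expect_equal(length(back$frames), 20)
  expect_equal(back$frame_times, st$frame_times)
  err <- max(abs(back$frames[[10]] - st$frames[[10]]))
  expect_lt(err, 1e-4)  # 32-bit float resolution of the scaled range
})
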