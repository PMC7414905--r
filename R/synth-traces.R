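#' Flight-trace simulation configuration
#'
#' @param duration Length of the continuous-flight phase after take-off (s);
#'   at least 40 s, the minimum flight accepted for analysis.
#' @param frame_rate Sampling rate of the thermal video (Hz).
#' @param takeoff_time Time of take-off from the start of the recording (s);
#'   the pre-take-off phase carries the warm-up.
#' @param t_env_base Baseline environment temperature (degrees C).
#' @param seed RNG seed; `NULL` leaves the RNG state alone.
#' @return An object of class `trace_sim_config`.
#' @export
trace_sim_config <- function(duration = 40, frame_rate = 25,
                             takeoff_time = 5, t_env_base = 25,
                             seed = NULL) {
  stop_if_not_scalar(duration, "duration")
  stop_if_not_scalar(frame_rate, "frame_rate")
  stop_if_not_scalar(takeoff_time, "takeoff_time")
  stop_if_not_scalar(t_env_base, "t_env_base")
  if (duration < 40) stop("'duration' must be >= 40 s (minimum analysable flight)")
  if (frame_rate <= 0) stop("'frame_rate' must be > 0")
  if (takeoff_time < 0) stop("'takeoff_time' must be >= 0")
  structure(list(duration = duration, frame_rate = frame_rate,
                 takeoff_time = takeoff_time, t_env_base = t_env_base,
                 seed = seed),
            class = "trace_sim_config")
}

#' Simulate thorax, abdomen and environment temperature traces for one flight
#'
#' Generates the three region-of-interest traces of a tethered-flight
#' thermography recording. The environment trace drifts linearly from its
#' baseline; the thorax excess (thorax minus environment) rises during the
#' pre-take-off warm-up by exponential saturation and during flight follows a
#' line centred on the flight window, so that at zero noise the mean thorax
#' excess over the flight window equals `endothermy_true` exactly and the
#' least-squares flight slope equals `slope_th_true` exactly. The abdomen
#' carries a mechanism-dependent fraction of the thorax excess (small for
#' abdominal passive heat transfer, large for active transfer) plus its own
#' flight slope. I.i.d. Gaussian noise of sd `noise_sd` is added per frame to
#' each trace.
#'
#' @param profile A [species_profile()].
#' @param cfg A [trace_sim_config()].
#' @return A list of class `flight_trace_sim` with elements `t_th`, `t_abd`,
#'   `t_env` (each a [temp_trace()]), `window` (a [flight_window()]) and
#'   `truth`, the ground-truth record of every generating parameter:
#'   `endothermy_true` / `slope_*_true` are this individual's drawn values
#'   (the analytic noise-free mean excess and slopes of its traces), and
#'   `endothermy_species` / `slope_*_species` the species-level means they
#'   were drawn around.
#' @export
simulate_flight_trace <- function(profile, cfg = trace_sim_config()) {
  stopifnot(inherits(profile, "species_profile"),
            inherits(cfg, "trace_sim_config"))
  n_pre <- round(cfg$takeoff_time * cfg$frame_rate)
  n_fly <- round(cfg$duration * cfg$frame_rate)
  times <- seq(0, by = 1 / cfg$frame_rate, length.out = n_pre + n_fly + 1L)
  takeoff <- times[n_pre + 1L]
  mid <- takeoff + cfg$duration / 2
  f <- profile$abd_excess_frac

  res <- with_seed(cfg$seed, {
    # individual-level true parameters around the species means
    draw <- function(mu, sd) if (sd > 0) stats::rnorm(1, mu, sd) else mu
    endo <- max(draw(profile$endothermy_true, profile$endothermy_sd), 0)
    s_th <- draw(profile$slope_th_true, profile$slope_th_sd)
    s_abd <- draw(profile$slope_abd_true, profile$slope_abd_sd)
    s_env <- draw(profile$slope_env_true, profile$slope_env_sd)

    env_clean <- cfg$t_env_base + s_env * times

    # thorax excess over environment
    excess_takeoff <- endo - s_th * cfg$duration / 2
    wamp <- profile$warmup_amplitude %||% excess_takeoff
    excess_th <- numeric(length(times))
    pre <- times < takeoff
    if (any(pre)) {
      sat <- 1 - exp(-profile$warmup_rate * times[pre])
      sat_at_takeoff <- 1 - exp(-profile$warmup_rate * takeoff)
      excess_th[pre] <- wamp * sat / sat_at_takeoff
    }
    fly <- !pre
    excess_th[fly] <- endo + s_th * (times[fly] - mid)

    # abdomen excess: a fraction of the thorax excess shape, own flight slope
    excess_abd <- numeric(length(times))
    excess_abd[pre] <- f * excess_th[pre]
    excess_abd[fly] <- f * endo + s_abd * (times[fly] - mid)

    noise <- function(n) {
      if (profile$noise_sd > 0) stats::rnorm(n, 0, profile$noise_sd) else 0
    }
    n <- length(times)
    list(env = env_clean + noise(n),
         th = env_clean + excess_th + noise(n),
         abd = env_clean + excess_abd + noise(n),
         endo = endo, s_th = s_th, s_abd = s_abd, s_env = s_env,
         wamp = wamp)
  })

  window <- flight_window(takeoff, times[length(times)])
  truth <- list(
    species = profile$name,
    endothermy_true = res$endo,
    slope_th_true = res$s_th,
    slope_abd_true = res$s_abd,
    slope_env_true = res$s_env,
    endothermy_species = profile$endothermy_true,
    slope_th_species = profile$slope_th_true,
    slope_abd_species = profile$slope_abd_true,
    mechanism_true = profile$mechanism_true,
    abd_excess_frac = f,
    warmup_amplitude = res$wamp,
    warmup_rate = profile$warmup_rate,
    noise_sd = profile$noise_sd,
    takeoff_time = takeoff,
    duration = cfg$duration,
    frame_rate = cfg$frame_rate,
    n_frames = length(times))
  vals <- res

  structure(list(
    t_th = temp_trace(times, vals$th, "thorax"),
    t_abd = temp_trace(times, vals$abd, "abdomen"),
    t_env = temp_trace(times, vals$env, "environment"),
    window = window,
    truth = truth), class = "flight_trace_sim")
}

#' @method print flight_trace_sim
#' @export
print.flight_trace_sim <- function(x, ...) {
  cat(sprintf("<flight_trace_sim> %s: %d frames @ %g Hz, take-off %g s, mechanism %s\n",
              x$truth$species, x$truth$n_frames, x$truth$frame_rate,
              x$truth$takeoff_time, x$truth$mechanism_true))
  invisible(x)
}

#' @describeIn simulate_flight_trace traces as a four-column data frame
#'   (`time_s`, `t_th`, `t_abd`, `t_env`).
#' @param x A `flight_trace_sim` object.
#' @param ... Unused.
#' @export
as.data.frame.flight_trace_sim <- function(x, ...) {
  data.frame(time_s = x$t_th$times, t_th = x$t_th$values,
             t_abd = x$t_abd$values, t_env = x$t_env$values)
}

#' Render simulated traces as a thermogram frame stack
#'
#' Builds a stack of temperature matrices in which three disjoint 3x3-pixel
#' patches carry the thorax, abdomen and environment trace values: within a
#' patch every pixel is at most the nominal trace value and the patch maximum
#' equals it exactly (pixels decay away from the patch centre), so a
#' maximum-over-ROI extractor recovers the traces. The background is the
#' environment trace value. Patches can be jittered by up to `jitter_px`
#' pixels per frame to emulate body movement; jitter of <= 1 px is absorbed by
#' a 3x3 maximum window at the nominal centre.
#'
#' @param sim A `flight_trace_sim` from [simulate_flight_trace()].
#' @param rows,cols Frame dimensions (pixels).
#' @param centers Named list of `c(row, col)` patch centres (1-based) for
#'   `thorax`, `abdomen`, `environment`.
#' @param jitter_px Maximum per-frame patch displacement (pixels).
#' @param seed RNG seed for the jitter.
#' @return A [frame_stack()] with an `rois` attribute (data frame of nominal
#'   centres).
#' @export
simulate_frame_stack <- function(sim, rows = 32, cols = 32,
                                 centers = list(thorax = c(8, 8),
                                                abdomen = c(8, 24),
                                                environment = c(24, 16)),
                                 jitter_px = 0, seed = NULL) {
  stopifnot(inherits(sim, "flight_trace_sim"))
  stopifnot(setequal(names(centers), c("thorax", "abdomen", "environment")))
  if (jitter_px < 0 || jitter_px != round(jitter_px)) {
    stop("'jitter_px' must be a non-negative integer")
  }
  ctr <- do.call(rbind, centers)
  # pairwise disjointness of (possibly jittered) 3x3 windows
  for (i in 1:2) for (j in (i + 1):3) {
    if (max(abs(ctr[i, ] - ctr[j, ])) <= 2 + 2 * jitter_px) {
      stop("ROI patches overlap (or can overlap under jitter); move centers apart")
    }
  }
  margin <- 1 + jitter_px
  if (any(ctr - margin < 1) || any(ctr[, 1] + margin > rows) ||
      any(ctr[, 2] + margin > cols)) {
    stop("ROI patch (plus jitter) falls outside the frame")
  }

  traces <- list(thorax = sim$t_th$values, abdomen = sim$t_abd$values,
                 environment = sim$t_env$values)
  nf <- length(sim$t_th$times)
  # fixed decay pattern: centre pixel holds the nominal value
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  decay <- 0.2 * (abs(offs$dr) + abs(offs$dc))

  frames <- with_seed(seed, lapply(seq_len(nf), function(k) {
    fr <- matrix(traces$environment[k], nrow = rows, ncol = cols)
    for (lab in names(centers)) {
      jit <- if (jitter_px > 0) {
        c(sample(-jitter_px:jitter_px, 1), sample(-jitter_px:jitter_px, 1))
      } else c(0L, 0L)
      rc <- centers[[lab]] + jit
      v <- traces[[lab]][k]
      fr[cbind(rc[1] + offs$dr, rc[2] + offs$dc)] <- v - decay
    }
    fr
  }))

  st <- frame_stack(frames, sim$t_th$times)
  attr(st, "rois") <- data.frame(
    label = names(centers),
    center_row = ctr[, 1], center_col = ctr[, 2], row.names = NULL)
  st
}
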