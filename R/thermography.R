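#' Temperature trace for one region of interest
#'
#' @param times Sample times (s), strictly increasing.
#' @param values Temperatures (degrees C), finite, same length as `times`.
#' @param roi ROI label (`"thorax"`, `"abdomen"`, `"environment"` or other).
#' @param corrected Whether the radiometric correction has been applied.
#' @return An object of class `temp_trace`.
#' @export
temp_trace <- function(times, values, roi = "thorax", corrected = FALSE) {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values)) stop("times/values length mismatch")
  if (length(times) == 0L) stop("empty trace")
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  if (!all(is.finite(values))) stop("trace values must be finite")
  structure(list(times = times, values = values, roi = roi,
                 corrected = isTRUE(corrected)), class = "temp_trace")
}

#' @method print temp_trace
#' @export
print.temp_trace <- function(x, ...) {
  cat(sprintf("<temp_trace> %s: %d samples over %.1f s, %.2f-%.2f degC%s\n",
              x$roi, length(x$times), diff(range(x$times)),
              min(x$values), max(x$values),
              if (x$corrected) " (corrected)" else ""))
  invisible(x)
}

#' Thermogram frame stack
#'
#' @param frames List of numeric matrices (temperatures in degrees C), all of
#'   the same dimensions.
#' @param frame_times Frame times (s), strictly increasing, one per frame.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, frame_times) {
  if (length(frames) == 0L) stop("empty frame stack")
  if (length(frames) != length(frame_times)) {
    stop("one frame time per frame required")
  }
  if (any(diff(frame_times) <= 0)) stop("frame_times must be strictly increasing")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all frames must share the same dimensions")
  }
  structure(list(frames = frames, frame_times = as.numeric(frame_times),
                 shape = dims[, 1]), class = "frame_stack")
}

#' @method print frame_stack
#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("<frame_stack> %d frames of %dx%d px, %.1f s\n",
              length(x$frames), x$shape[1], x$shape[2],
              diff(range(x$frame_times))))
  invisible(x)
}

#' Flight window of a tethered-flight recording
#'
#' Continuous flight must last at least `min_duration` seconds (default 40 s)
#' for the individual to enter the analysis; shorter recordings are flagged
#' `qualifies = FALSE`.
#'
#' @param takeoff_time,end_time Window bounds (s), `end_time > takeoff_time`.
#' @param min_duration Minimum qualifying flight duration (s).
#' @return An object of class `flight_window` with a `qualifies` flag.
#' @export
flight_window <- function(takeoff_time, end_time, min_duration = 40) {
  stop_if_not_scalar(takeoff_time, "takeoff_time")
  stop_if_not_scalar(end_time, "end_time")
  if (end_time <= takeoff_time) stop("end_time must exceed takeoff_time")
  structure(list(takeoff_time = takeoff_time, end_time = end_time,
                 qualifies = (end_time - takeoff_time) >= min_duration,
                 min_duration = min_duration),
            class = "flight_window")
}

#' @method print flight_window
#' @export
print.flight_window <- function(x, ...) {
  cat(sprintf("<flight_window> [%.2f, %.2f] s (%.1f s) - %s\n",
              x$takeoff_time, x$end_time, x$end_time - x$takeoff_time,
              if (x$qualifies) "qualifies" else "does NOT qualify"))
  invisible(x)
}

#' Extract the maximum-temperature trace of a 3x3 ROI
#'
#' Per frame, the trace value is the maximum over the 3x3 pixel window centred
#' on the ROI. The maximum (rather than the mean) is used because moving legs
#' crossing the ROI bias individual pixels low.
#'
#' @param stack A [frame_stack()].
#' @param center_row,center_col ROI centre (1-based pixel indices); the 3x3
#'   window must lie fully inside the frame.
#' @param roi ROI label attached to the returned trace.
#' @return An uncorrected [temp_trace()].
#' @examples
#' st <- frame_stack(list(matrix(20:28, 3, 3)), 0.04)
#' extract_roi_trace(st, 2, 2)$values  # max of the 3x3 block
#' @export
extract_roi_trace <- function(stack, center_row, center_col, roi = "thorax") {
  stopifnot(inherits(stack, "frame_stack"))
  stop_if_not_scalar(center_row, "center_row")
  stop_if_not_scalar(center_col, "center_col")
  if (center_row < 2 || center_col < 2 ||
      center_row > stack$shape[1] - 1 || center_col > stack$shape[2] - 1) {
    stop("3x3 ROI window falls outside the frame")
  }
  rr <- (center_row - 1):(center_row + 1)
  cc <- (center_col - 1):(center_col + 1)
  vals <- vapply(stack$frames, function(fr) max(fr[rr, cc]), numeric(1))
  temp_trace(stack$frame_times, vals, roi = roi, corrected = FALSE)
}

#' Radiometric correction parameters
#'
#' Parameters of the single-reflection greybody model used to convert
#' apparent (blackbody-equivalent) infrared temperatures to true surface
#' temperatures: surface emissivity, reflected ambient temperature,
#' atmospheric (air) temperature and path transmittance. At the short working
#' distances of tethered-flight recordings the atmospheric transmittance is
#' effectively 1, the default.
#'
#' @param emissivity Surface emissivity in (0, 1].
#' @param reflected_temp Reflected apparent temperature (degrees C).
#' @param air_temp Atmospheric temperature (degrees C); only used when
#'   `transmittance < 1`.
#' @param distance Camera-to-object distance (m); recorded metadata, not used
#'   numerically (it is subsumed in `transmittance`).
#' @param relative_humidity Relative humidity as a fraction; recorded
#'   metadata, subsumed in `transmittance`.
#' @param transmittance Atmospheric path transmittance in (0, 1].
#' @return An object of class `radiometric_params`.
#' @export
radiometric_params <- function(emissivity = 0.95, reflected_temp = 25,
                               air_temp = 25, distance = 0.5,
                               relative_humidity = 0.5, transmittance = 1) {
  stop_if_not_scalar(emissivity, "emissivity")
  stop_if_not_scalar(transmittance, "transmittance")
  if (emissivity <= 0 || emissivity > 1) stop("emissivity must be in (0, 1]")
  if (transmittance <= 0 || transmittance > 1) {
    stop("transmittance must be in (0, 1]")
  }
  structure(list(emissivity = emissivity, reflected_temp = reflected_temp,
                 air_temp = air_temp, distance = distance,
                 relative_humidity = relative_humidity,
                 transmittance = transmittance),
            class = "radiometric_params")
}

# T^4 radiance proxy in Kelvin^4 and its inverse (degrees C in/out).
.w <- function(t_c) (t_c + 273.15)^4
.w_inv <- function(w) {
  if (any(w <= 0)) stop("non-physical radiance (temperature below 0 K)")
  w^0.25 - 273.15
}

#' Correct an apparent temperature trace for emissivity and reflection
#'
#' Inverts the single-reflection greybody model on the T^4 radiance scale:
#' `W_obj = (W_meas - (1 - e) * tau * W_refl - (1 - tau) * W_atm) / (e * tau)`
#' with `W(T)` proportional to absolute temperature to the fourth power. With
#' emissivity and transmittance 1 the correction is the identity; it is
#' monotone increasing in the apparent value for any valid parameters.
#'
#' @param apparent An uncorrected [temp_trace()] of apparent temperatures.
#' @param params A [radiometric_params()].
#' @return A corrected [temp_trace()].
#' @export
correct_temperature <- function(apparent, params) {
  stopifnot(inherits(apparent, "temp_trace"),
            inherits(params, "radiometric_params"))
  if (apparent$corrected) stop("trace is already corrected")
  e <- params$emissivity
  tau <- params$transmittance
  w_obj <- (.w(apparent$values) - (1 - e) * tau * .w(params$reflected_temp) -
              (1 - tau) * .w(params$air_temp)) / (e * tau)
  temp_trace(apparent$times, .w_inv(w_obj), roi = apparent$roi,
             corrected = TRUE)
}

# Forward greybody model: apparent (blackbody-equivalent) temperature of a
# surface at true temperature t_c. Used by the emissivity estimator and as
# the round-trip oracle in tests.
apparent_temperature <- function(t_c, params) {
  e <- params$emissivity
  tau <- params$transmittance
  .w_inv(e * tau * .w(t_c) + (1 - e) * tau * .w(params$reflected_temp) +
           (1 - tau) * .w(params$air_temp))
}

#' Estimate cuticle emissivity against a reference emitter
#'
#' Cuticle and a reference tape of known emissivity are held at the same
#' (unknown) true temperatures over a range (e.g. 50-80 degrees C) and their
#' apparent infrared temperatures recorded. On the T^4 radiance scale the
#' greybody model gives, for each pair, `W_cut - W_refl = e * (W_true -
#' W_refl)` with `W_true` recovered from the reference reading via its known
#' emissivity; the cuticle emissivity is the least-squares slope through the
#' origin of those differences, clipped to (0, 1].
#'
#' @param cuticle_apparent,reference_apparent Paired apparent temperatures
#'   (degrees C) at matched true temperatures; at least 2 pairs.
#' @param epsilon_ref Reference emissivity (default 0.95, electrical tape).
#' @param reflected_temp Reflected ambient apparent temperature (degrees C).
#' @return Estimated emissivity (scalar in (0, 1]).
#' @export
estimate_emissivity <- function(cuticle_apparent, reference_apparent,
                                epsilon_ref = 0.95, reflected_temp = 25) {
  if (length(cuticle_apparent) != length(reference_apparent)) {
    stop("paired measurements required")
  }
  if (length(cuticle_apparent) < 2) stop("at least 2 measurement pairs required")
  if (epsilon_ref <= 0 || epsilon_ref > 1) stop("epsilon_ref must be in (0, 1]")
  w_refl <- .w(reflected_temp)
  w_true <- (.w(reference_apparent) - (1 - epsilon_ref) * w_refl) / epsilon_ref
  x <- w_true - w_refl
  y <- .w(cuticle_apparent) - w_refl
  if (sum(x^2) == 0) stop("zero-variance inputs: reference never departs from the reflected temperature")
  e <- sum(x * y) / sum(x^2)
  min(max(e, .Machine$double.eps), 1)
}

#' Detect the flight window of a thorax trace
#'
#' If a take-off annotation is supplied it is used verbatim; otherwise
#' take-off is placed at the largest forward difference of the trace (the
#' take-off transient is the steepest warming in a tethered-flight recording).
#' The window runs to the end of the trace and qualifies only when it spans at
#' least `min_duration` seconds.
#'
#' @param trace A thorax [temp_trace()].
#' @param takeoff_time Optional annotated take-off time (s).
#' @param min_duration Minimum qualifying flight duration (s), default 40.
#' @return A [flight_window()] (with `qualifies = FALSE` rather than an error
#'   for short traces).
#' @export
detect_flight_window <- function(trace, takeoff_time = NULL,
                                 min_duration = 40) {
  stopifnot(inherits(trace, "temp_trace"))
  end_time <- trace$times[length(trace$times)]
  if (is.null(takeoff_time)) {
    if (length(trace$times) < 2) {
      takeoff_time <- trace$times[1]
    } else {
      d <- diff(trace$values)
      takeoff_time <- trace$times[which.max(d) + 1L]
    }
  }
  if (end_time <= takeoff_time) {
    return(structure(list(takeoff_time = takeoff_time, end_time = end_time,
                          qualifies = FALSE, min_duration = min_duration),
                     class = "flight_window"))
  }
  flight_window(takeoff_time, end_time, min_duration = min_duration)
}

#' Write / read a frame stack as a multi-page grayscale TIFF
#'
#' Grayscale TIFF samples live in \[0, 1\], so temperatures are mapped
#' linearly onto that range and stored as 32-bit floats; the affine scale
#' (`t_min`, `t_max`) and the frame times go to a CSV sidecar
#' (`<stem>_times.csv` by default), since baseline TIFF carries neither
#' radiometric scaling nor per-page timing. Round-trip precision is the
#' 32-bit float resolution of the stored range (~1e-5 degrees C for typical
#' scenes).
#'
#' @param stack A [frame_stack()].
#' @param path TIFF file path.
#' @param times_path Frame-time + scale sidecar CSV path.
#' @return `write_frame_stack` returns `path` invisibly; `read_frame_stack`
#'   returns a [frame_stack()].
#' @export
write_frame_stack <- function(stack, path,
                              times_path = sub("\\.tiff?$", "_times.csv", path)) {
  stopifnot(inherits(stack, "frame_stack"))
  t_min <- min(vapply(stack$frames, min, numeric(1)))
  t_max <- max(vapply(stack$frames, max, numeric(1)))
  span <- if (t_max > t_min) t_max - t_min else 1
  scaled <- lapply(stack$frames, function(fr) (fr - t_min) / span)
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L, reduce = FALSE)
  utils::write.csv(data.frame(frame = seq_along(stack$frame_times),
                              time_s = stack$frame_times,
                              t_min = t_min, t_max = t_max),
                   times_path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frame_stack
#' @export
read_frame_stack <- function(path,
                             times_path = sub("\\.tiff?$", "_times.csv", path)) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  sidecar <- utils::read.csv(times_path)
  t_min <- sidecar$t_min[1]
  span <- if (sidecar$t_max[1] > t_min) sidecar$t_max[1] - t_min else 1
  frames <- lapply(frames, function(fr) fr * span + t_min)
  frame_stack(frames, sidecar$time_s)
}
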