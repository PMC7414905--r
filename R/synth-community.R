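#' Community abundance simulation configuration
#'
#' Abundances are negative-binomial per species-by-site, with a species' mean
#' set to `mean_own` at sites of its true habitat and `mean_other` elsewhere.
#' `mean_other = 0` plants a perfect-specificity species; `mean_other =
#' mean_own` yields a habitat-unstructured (null) community.
#'
#' @param species Character vector of species names, or a list of
#'   [species_profile()]s (their `habitat_true` is used).
#' @param habitat_true Habitat per species (recycled if scalar); ignored when
#'   `species` is a profile list.
#' @param habitats Habitat labels (>= 2).
#' @param sites_per_habitat Replicate sites per habitat (>= 2).
#' @param mean_own,mean_other Negative-binomial means in own/other habitats
#'   (recycled across species).
#' @param dispersion Negative-binomial size parameter (recycled).
#' @param seed RNG seed.
#' @return An object of class `community_sim_config`.
#' @export
community_sim_config <- function(species,
                                 habitat_true = NULL,
                                 habitats = c("native_forest", "agroforestry",
                                              "open_pasture"),
                                 sites_per_habitat = 3,
                                 mean_own = 30, mean_other = 2,
                                 dispersion = 2, seed = NULL) {
  if (is.list(species) && all(vapply(species, inherits, logical(1),
                                     "species_profile"))) {
    habitat_true <- vapply(species, function(p) p$habitat_true, character(1))
    species <- vapply(species, function(p) p$name, character(1))
  }
  n <- length(species)
  if (n == 0) stop("at least one species required")
  if (sites_per_habitat < 2) stop("'sites_per_habitat' must be >= 2")
  if (length(habitats) < 2) stop("at least 2 habitats required")
  habitat_true <- rep_len(habitat_true %||% habitats[1], n)
  if (!all(habitat_true %in% habitats)) {
    stop("every habitat_true must be one of 'habitats'")
  }
  structure(list(species = species, habitat_true = habitat_true,
                 habitats = habitats, sites_per_habitat = sites_per_habitat,
                 mean_own = rep_len(mean_own, n),
                 mean_other = rep_len(mean_other, n),
                 dispersion = rep_len(dispersion, n), seed = seed),
            class = "community_sim_config")
}

#' Simulate a site-by-species abundance matrix with planted indicators
#'
#' @param cfg A [community_sim_config()].
#' @return A list of class `community_sim`: `counts` (site-by-species integer
#'   matrix), `habitat_of_site`, and `truth`, a data frame recording each
#'   species' true habitat, the generating means/dispersion and whether it was
#'   planted as a perfect-specificity indicator (`mean_other == 0`).
#' @export
simulate_community <- function(cfg) {
  stopifnot(inherits(cfg, "community_sim_config"))
  sites <- paste(rep(cfg$habitats, each = cfg$sites_per_habitat),
                 rep(seq_len(cfg$sites_per_habitat), length(cfg$habitats)),
                 sep = "_")
  hab_of_site <- rep(cfg$habitats, each = cfg$sites_per_habitat)
  n_sites <- length(sites)
  counts <- with_seed(cfg$seed, {
    m <- sapply(seq_along(cfg$species), function(i) {
      mu <- ifelse(hab_of_site == cfg$habitat_true[i],
                   cfg$mean_own[i], cfg$mean_other[i])
      stats::rnbinom(n_sites, size = cfg$dispersion[i], mu = mu)
    })
    matrix(m, nrow = n_sites,
           dimnames = list(sites, cfg$species))
  })
  truth <- data.frame(species = cfg$species,
                      habitat_true = cfg$habitat_true,
                      mean_own = cfg$mean_own, mean_other = cfg$mean_other,
                      dispersion = cfg$dispersion,
                      planted_indicator = cfg$mean_other == 0,
                      stringsAsFactors = FALSE)
  structure(list(counts = counts, habitat_of_site = hab_of_site,
                 truth = truth), class = "community_sim")
}

#' Capture-schedule simulation configuration
#'
#' @param species Species names.
#' @param diurnal_fraction Probability that a capture falls in the daytime
#'   period (recycled across species; in \[0, 1\]).
#' @param total_captures Captures per species (recycled; > 0).
#' @param days Sampling days (default 5 full days).
#' @param day_start,day_end Daytime period bounds (hours).
#' @param start_date First sampling date.
#' @param seed RNG seed.
#' @return An object of class `capture_sim_config`.
#' @export
capture_sim_config <- function(species, diurnal_fraction = 0.5,
                               total_captures = 50, days = 5,
                               day_start = 7, day_end = 18,
                               start_date = "2015-11-01", seed = NULL) {
  n <- length(species)
  if (n == 0) stop("at least one species required")
  diurnal_fraction <- rep_len(diurnal_fraction, n)
  total_captures <- rep_len(total_captures, n)
  if (any(diurnal_fraction < 0 | diurnal_fraction > 1)) {
    stop("'diurnal_fraction' must be in [0, 1]")
  }
  if (any(total_captures <= 0)) stop("'total_captures' must be positive")
  if (days < 1) stop("'days' must be >= 1")
  structure(list(species = species, diurnal_fraction = diurnal_fraction,
                 total_captures = total_captures, days = days,
                 day_start = day_start, day_end = day_end,
                 start_date = start_date, seed = seed),
            class = "capture_sim_config")
}

#' Simulate pitfall capture records with timestamps
#'
#' Each capture lands in the daytime period with its species'
#' `diurnal_fraction` probability (binomial), on a uniformly chosen sampling
#' day and a uniform clock time within the period (the night period spans
#' midnight).
#'
#' @param cfg A [capture_sim_config()].
#' @return A list of class `capture_sim`: `captures` (data frame `species`,
#'   `timestamp`) and `truth` (per-species `diurnal_fraction`,
#'   `total_captures`, and the implied true activity label at the 60% rule).
#' @export
simulate_captures <- function(cfg) {
  stopifnot(inherits(cfg, "capture_sim_config"))
  day_len <- cfg$day_end - cfg$day_start
  night_len <- 24 - day_len
  base <- as.POSIXct(paste(cfg$start_date, "00:00:00"), tz = "UTC")
  rows <- with_seed(cfg$seed, {
    lapply(seq_along(cfg$species), function(i) {
      n <- cfg$total_captures[i]
      in_day <- stats::rbinom(n, 1, cfg$diurnal_fraction[i]) == 1
      day_idx <- sample(cfg$days, n, replace = TRUE) - 1
      u <- stats::runif(n)
      hour <- ifelse(in_day, cfg$day_start + u * day_len,
                     (cfg$day_end + u * night_len) %% 24)
      data.frame(species = cfg$species[i],
                 timestamp = format(base + day_idx * 86400 + hour * 3600,
                                    "%Y-%m-%d %H:%M:%S"),
                 stringsAsFactors = FALSE)
    })
  })
  truth <- data.frame(
    species = cfg$species,
    diurnal_fraction = cfg$diurnal_fraction,
    total_captures = cfg$total_captures,
    activity_true = ifelse(cfg$diurnal_fraction >= 0.6, "diurnal",
                           ifelse(cfg$diurnal_fraction <= 0.4, "ENC",
                                  "unresolved")),
    stringsAsFactors = FALSE)
  structure(list(captures = do.call(rbind, rows), truth = truth),
            class = "capture_sim")
}

#' Sensor-log simulation configuration
#'
#' The diel cycle is a cosine peaking at `peak_hour` (default 14:00, the
#' hottest part of the afternoon): `temp(t) = diel_mean + diel_amplitude *
#' cos(2 * pi * (hour - peak_hour) / 24) + noise`. With the default day
#' window (7:00-18:00) the analytic day maximum is `diel_mean +
#' diel_amplitude` and the night minimum `diel_mean - diel_amplitude`, so the
#' downstream thermal amplitude is `2 * diel_amplitude`.
#'
#' @param days Record length in days (default 12).
#' @param interval_min Sampling interval in minutes (default 5); must divide
#'   1440.
#' @param diel_mean,diel_amplitude Cosine mean and semi-amplitude (degrees C).
#' @param peak_hour Clock hour of the daily maximum.
#' @param noise_sd Gaussian noise sd (degrees C).
#' @param site,habitat Labels carried into the log.
#' @param start_date First day of the record.
#' @param seed RNG seed.
#' @return An object of class `sensor_sim_config`.
#' @export
sensor_sim_config <- function(days = 12, interval_min = 5, diel_mean = 22,
                              diel_amplitude = 5, peak_hour = 14,
                              noise_sd = 0.2, site = "site_1",
                              habitat = "native_forest",
                              start_date = "2015-10-01", seed = NULL) {
  if (days < 1) stop("'days' must be >= 1")
  if (interval_min <= 0 || 1440 %% interval_min != 0) {
    stop("'interval_min' must divide 1440")
  }
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  structure(list(days = days, interval_min = interval_min,
                 diel_mean = diel_mean, diel_amplitude = diel_amplitude,
                 peak_hour = peak_hour, noise_sd = noise_sd, site = site,
                 habitat = habitat, start_date = start_date, seed = seed),
            class = "sensor_sim_config")
}

#' Simulate a fixed-interval ground-temperature log
#'
#' @param cfg A [sensor_sim_config()].
#' @return A list of class `sensor_sim`: `log` (data frame `timestamp`,
#'   `temp_c`, `site`, `habitat`) and `truth` with the generating parameters
#'   and the analytic day-max / night-min / amplitude implied by the cosine.
#' @export
simulate_sensor_log <- function(cfg) {
  stopifnot(inherits(cfg, "sensor_sim_config"))
  n <- cfg$days * 1440 / cfg$interval_min
  base <- as.POSIXct(paste(cfg$start_date, "00:00:00"), tz = "UTC")
  ts <- base + (seq_len(n) - 1) * cfg$interval_min * 60
  hour <- (as.numeric(ts - base, units = "hours")) %% 24
  clean <- cfg$diel_mean +
    cfg$diel_amplitude * cos(2 * pi * (hour - cfg$peak_hour) / 24)
  temps <- with_seed(cfg$seed, {
    clean + if (cfg$noise_sd > 0) stats::rnorm(n, 0, cfg$noise_sd) else 0
  })
  truth <- list(diel_mean = cfg$diel_mean,
                diel_amplitude = cfg$diel_amplitude,
                peak_hour = cfg$peak_hour, noise_sd = cfg$noise_sd,
                day_max_expected = cfg$diel_mean + cfg$diel_amplitude,
                night_min_expected = cfg$diel_mean - cfg$diel_amplitude,
                amplitude_expected = 2 * cfg$diel_amplitude)
  structure(list(
    log = data.frame(timestamp = format(ts, "%Y-%m-%d %H:%M:%S"),
                     temp_c = temps, site = cfg$site, habitat = cfg$habitat,
                     stringsAsFactors = FALSE),
    truth = truth), class = "sensor_sim")
}
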