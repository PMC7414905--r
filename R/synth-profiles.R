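#' Construct a species ground-truth profile for simulation
#'
#' A `species_profile` holds the "true" thermal-niche parameters of one
#' simulated species: body mass distribution, endothermy (mean thorax minus
#' environment temperature during flight, in degrees C), warm-up dynamics,
#' the true thorax/abdomen temperature slopes during flight (degrees C/s), the
#' physiological thermoregulation mechanism the species is built to exhibit,
#' and the per-frame measurement noise.
#'
#' @param name Species label.
#' @param activity True daily activity, `"diurnal"` or `"ENC"`
#'   (evening/nocturnal/crepuscular).
#' @param habitat True habitat affinity: `"native_forest"`, `"agroforestry"`
#'   or `"open_pasture"`.
#' @param mass_mean,mass_sd Body mass distribution (g); individuals are drawn
#'   from a normal truncated at a small positive floor.
#' @param endothermy_true True excess temperature: the mean of
#'   `T_th - T_env` over the flight window at zero noise (degrees C, >= 0).
#' @param endothermy_sd Between-individual sd of the excess temperature
#'   (degrees C); each simulated flight draws its own endothermy from a
#'   normal truncated at 0.
#' @param warmup_amplitude Saturation level of the pre-take-off warm-up excess
#'   (degrees C). Defaults to the thorax excess at take-off so the trace is
#'   continuous; set it lower to create a step at take-off.
#' @param warmup_rate Exponential warm-up rate (1/s).
#' @param slope_th_true,slope_abd_true True flight-phase slopes of the thorax
#'   and abdomen traces (degrees C/s), the species means.
#' @param slope_env_true True drift of the environment trace (degrees C/s).
#' @param slope_th_sd,slope_abd_sd,slope_env_sd Between-individual sd of the
#'   respective slopes (degrees C/s); 0 (the default) gives every individual
#'   the species-mean slope.
#' @param mechanism_true Planted thermoregulation mechanism: `"APHT"`
#'   (abdominal passive heat transfer: thorax warms, abdomen stays near the
#'   environment), `"AAHT"` (abdominal active heat transfer: abdomen tracks
#'   the thorax) or `"NONE"`.
#' @param abd_excess_frac Fraction of the thorax excess carried by the abdomen
#'   (dimensionless); defaults to 0.15 for APHT/NONE and 0.8 for AAHT.
#' @param noise_sd Per-frame i.i.d. Gaussian measurement noise (degrees C).
#' @return An object of class `species_profile` (a named list).
#' @examples
#' sp <- species_profile("demo", endothermy_true = 5, mechanism_true = "APHT",
#'                       slope_th_true = 0.02)
#' @export
species_profile <- function(name,
                            activity = c("diurnal", "ENC"),
                            habitat = c("native_forest", "agroforestry",
                                        "open_pasture"),
                            mass_mean = 0.3, mass_sd = 0.05,
                            endothermy_true = 4,
                            endothermy_sd = 0,
                            warmup_amplitude = NULL,
                            warmup_rate = 1,
                            slope_th_true = 0,
                            slope_abd_true = 0,
                            slope_env_true = 0,
                            slope_th_sd = 0,
                            slope_abd_sd = 0,
                            slope_env_sd = 0,
                            mechanism_true = c("NONE", "APHT", "AAHT"),
                            abd_excess_frac = NULL,
                            noise_sd = 0.3) {
  activity <- match.arg(activity)
  habitat <- match.arg(habitat)
  mechanism_true <- match.arg(mechanism_true)
  for (nm in c("mass_mean", "mass_sd", "endothermy_true", "endothermy_sd",
               "warmup_rate", "slope_th_true", "slope_abd_true",
               "slope_env_true", "slope_th_sd", "slope_abd_sd",
               "slope_env_sd", "noise_sd")) {
    stop_if_not_scalar(get(nm), nm)
  }
  if (mass_mean <= 0) stop("'mass_mean' must be > 0")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (endothermy_sd < 0 || slope_th_sd < 0 || slope_abd_sd < 0 ||
      slope_env_sd < 0) {
    stop("between-individual sds must be >= 0")
  }
  if (endothermy_true < 0) stop("'endothermy_true' must be >= 0")
  if (mechanism_true %in% c("APHT", "AAHT") && slope_th_true <= 0) {
    stop("mechanism '", mechanism_true, "' requires slope_th_true > 0")
  }
  if (mechanism_true == "AAHT" && slope_abd_true <= 0) {
    stop("mechanism 'AAHT' requires slope_abd_true > 0")
  }
  if (is.null(abd_excess_frac)) {
    abd_excess_frac <- if (mechanism_true == "AAHT") 0.8 else 0.15
  }
  structure(
    list(name = name, activity_true = activity, habitat_true = habitat,
         mass_mean = mass_mean, mass_sd = mass_sd,
         endothermy_true = endothermy_true,
         endothermy_sd = endothermy_sd,
         warmup_amplitude = warmup_amplitude,
         warmup_rate = warmup_rate,
         slope_th_true = slope_th_true,
         slope_abd_true = slope_abd_true,
         slope_env_true = slope_env_true,
         slope_th_sd = slope_th_sd,
         slope_abd_sd = slope_abd_sd,
         slope_env_sd = slope_env_sd,
         mechanism_true = mechanism_true,
         abd_excess_frac = abd_excess_frac,
         noise_sd = noise_sd),
    class = "species_profile")
}

#' @method print species_profile
#' @export
print.species_profile <- function(x, ...) {
  cat(sprintf("<species_profile> %s (%s, %s)\n", x$name, x$activity_true,
              x$habitat_true))
  cat(sprintf("  mass %.3f g, endothermy %.2f degC, slopes th %.4f / abd %.4f degC/s, mechanism %s\n",
              x$mass_mean, x$endothermy_true, x$slope_th_true,
              x$slope_abd_true, x$mechanism_true))
  invisible(x)
}

#' Published per-species thermal-niche summary table
#'
#' Loads the bundled per-species summary of 17 Atlantic-forest dung beetle
#' species: habitat, daily activity (and whether it was established from the
#' daily-activity sampling or from the literature), sample size, mean body
#' mass, mean endothermy, mean thorax/abdomen/environment temperature slopes,
#' and the Kruskal-Wallis H and p values for the two slope-pair comparisons
#' (thorax vs abdomen, abdomen vs environment).
#'
#' @return A data frame with one row per species.
#' @export
species_thermal_table <- function() {
  path <- system.file("extdata", "species_thermal_table.csv",
                      package = "thermoniche", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Default species pool mirroring the published assemblage
#'
#' Builds a list of [species_profile()] objects parameterised from the bundled
#' species table ([species_thermal_table()]): each species' true mass,
#' endothermy and thorax/abdomen slopes are set to the published means, its
#' habitat and activity to the published labels, and its mechanism to APHT for
#' *Coprophanaeus saphirinus* (the only species with a defined physiological
#' mechanism) and NONE otherwise.
#'
#' @param noise_sd Per-frame trace noise applied to every species (degrees C).
#' @return A named list of `species_profile` objects (17 species).
#' @export
default_species_pool <- function(noise_sd = 0.3) {
  tab <- species_thermal_table()
  pool <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    mech <- if (r$species == "Coprophanaeus saphirinus") "APHT" else "NONE"
    species_profile(
      name = r$species,
      activity = if (r$activity == "diurnal") "diurnal" else "ENC",
      habitat = r$habitat,
      mass_mean = r$mass_mean, mass_sd = r$mass_sd,
      endothermy_true = r$endothermy_mean,
      endothermy_sd = r$endothermy_sd,
      slope_th_true = r$slope_th,
      slope_abd_true = r$slope_abd,
      slope_env_true = r$slope_env,
      slope_th_sd = r$slope_th_sd,
      slope_abd_sd = r$slope_abd_sd,
      slope_env_sd = r$slope_env_sd,
      mechanism_true = mech,
      noise_sd = noise_sd)
  })
  names(pool) <- tab$species
  pool
}
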