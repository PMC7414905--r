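#' Configuration for a full synthetic pipeline run
#'
#' All thresholds default to the study's values: 40-s minimum flight, 0.05
#' significance level for slope-pair "similarity" and IndVal inference, 999
#' permutations, 7:00/18:00 period boundaries, 60% activity dominance, 5-day
#' capture sampling and 12-day sensor records.
#'
#' @param species_pool Named list of [species_profile()]s; defaults to the
#'   bundled 17-species assemblage ([default_species_pool()]).
#' @param n_individuals Flights per species; `NULL` uses the published
#'   per-species sample sizes where the pool matches the bundled table, else
#'   8.
#' @param alpha Significance level.
#' @param n_permutations IndVal permutations.
#' @param min_flight Minimum qualifying flight (s).
#' @param day_start,day_end Diel period boundaries (hours).
#' @param min_captures Minimum captures for a sampling-based activity call.
#' @param capture_days,sensor_days Sampling lengths (days).
#' @param sensor_amplitudes Named semi-amplitudes (degrees C) per habitat;
#'   the defaults give thermal amplitudes of 10 / 12 / 21 degrees C in
#'   native forest / agroforestry / open pasture.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(species_pool = default_species_pool(),
                       n_individuals = NULL,
                       alpha = 0.05, n_permutations = 999,
                       min_flight = 40, day_start = 7, day_end = 18,
                       min_captures = 25, capture_days = 5,
                       sensor_days = 12,
                       sensor_amplitudes = c(native_forest = 5,
                                             agroforestry = 6,
                                             open_pasture = 10.5),
                       seed = 1) {
  stopifnot(length(species_pool) >= 2,
            all(vapply(species_pool, inherits, logical(1), "species_profile")))
  structure(list(species_pool = species_pool,
                 n_individuals = n_individuals, alpha = alpha,
                 n_permutations = n_permutations, min_flight = min_flight,
                 day_start = day_start, day_end = day_end,
                 min_captures = min_captures, capture_days = capture_days,
                 sensor_days = sensor_days,
                 sensor_amplitudes = sensor_amplitudes, seed = seed),
            class = "run_config")
}

# Polynomial rolling hash of the deparsed config, for provenance headers.
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

write_stage_csv <- function(df, path, config, stage) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# thermoniche %s | seed=%s | config=%s", stage,
                     config$seed, config_hash(config)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline output CSV (skipping the provenance header)
#'
#' @param path CSV written by [run_pipeline()].
#' @return A data frame.
#' @export
read_stage_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Run the full synthetic thermal-niche pipeline
#'
#' Simulates every input (flight traces, community abundances, capture
#' schedules, sensor logs) from the configured species pool, then runs all
#' analysis stages: per-individual physiology (endothermy, slopes, take-off
#' temperature), species mechanism classification, IndVal with permutation
#' inference, daily-activity classification (with the true activity labels as
#' the literature fallback for low-capture species), diel microclimate
#' summaries per habitat, and the comparative statistics (log-endothermy
#' mixed model with type-III Wald tests and Tukey contrasts, body-mass
#' Kruskal-Wallis/Conover within activity classes, slope correlations).
#'
#' Everything is deterministic given `config$seed`; each output CSV starts
#' with a comment line recording the seed and a config hash.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with all stage results (`physiology`,
#'   `mechanisms`, `indval`, `activity`, `microclimate`, `anova`,
#'   `contrasts`, `kw_mass`, `correlations`, `truth`) and `files`, the paths
#'   written.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("thermo_run_")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pool <- config$species_pool
  seed <- config$seed

  # --- stage 1: flights + physiology ---------------------------------------
  tab <- tryCatch(species_thermal_table(), error = function(e) NULL)
  n_ind <- function(nm) {
    if (!is.null(config$n_individuals)) return(config$n_individuals)
    if (!is.null(tab) && nm %in% tab$species) return(tab$n[tab$species == nm])
    8L
  }
  phys <- list()
  k <- 0L
  for (sp in pool) {
    for (i in seq_len(n_ind(sp$name))) {
      k <- k + 1L
      cfg <- trace_sim_config(seed = child_seed(seed, k))
      sim <- simulate_flight_trace(sp, cfg)
      mass <- with_seed(child_seed(seed, k + 100000L),
                        max(stats::rnorm(1, sp$mass_mean, sp$mass_sd), 0.005))
      win <- detect_flight_window(sim$t_th,
                                  takeoff_time = sim$truth$takeoff_time,
                                  min_duration = config$min_flight)
      if (!win$qualifies) next
      phys[[k]] <- individual_physiology(
        sim$t_th, sim$t_abd, sim$t_env, win,
        individual_id = sprintf("%s_%02d", gsub("[^A-Za-z]", "_", sp$name), i),
        species = sp$name, mass = mass, activity = sp$activity_true,
        habitat = sp$habitat_true)
    }
  }
  physiology <- do.call(rbind, phys)
  mech <- classify_mechanisms(physiology, alpha = config$alpha)

  # --- stage 2: community + activity ---------------------------------------
  comm_cfg <- community_sim_config(pool, seed = child_seed(seed, 2L))
  comm <- simulate_community(comm_cfg)
  iv <- indval(comm$counts, comm$habitat_of_site,
               n_permutations = config$n_permutations,
               seed = child_seed(seed, 3L))

  act_true <- vapply(pool, function(p) p$activity_true, character(1))
  cap_cfg <- capture_sim_config(
    species = names(pool),
    diurnal_fraction = ifelse(act_true == "diurnal", 0.85, 0.15),
    total_captures = 40, days = config$capture_days,
    day_start = config$day_start, day_end = config$day_end,
    seed = child_seed(seed, 4L))
  caps <- simulate_captures(cap_cfg)
  activity <- classify_activities(caps$captures,
                                  min_captures = config$min_captures,
                                  literature = as.list(act_true),
                                  day_start = config$day_start,
                                  day_end = config$day_end)

  # --- stage 3: microclimate ------------------------------------------------
  diel <- do.call(rbind, lapply(seq_along(config$sensor_amplitudes), function(i) {
    hb <- names(config$sensor_amplitudes)[i]
    s_cfg <- sensor_sim_config(days = config$sensor_days,
                               diel_amplitude = config$sensor_amplitudes[[i]],
                               habitat = hb, site = paste0(hb, "_1"),
                               seed = child_seed(seed, 10L + i))
    sl <- simulate_sensor_log(s_cfg)
    cbind(habitat = hb,
          as.data.frame(summarize_sensor_log(sl$log,
                                             day_start = config$day_start,
                                             day_end = config$day_end)))
  }))

  # --- stage 4: comparative statistics -------------------------------------
  lmm <- fit_thermal_lmm(physiology, "endothermy", log_transform = TRUE)
  aov3 <- anova_type3(lmm)
  contr <- rbind(cbind(within = "activity", tukey_contrasts(lmm, "activity")),
                 cbind(within = "habitat", tukey_contrasts(lmm, "habitat")))
  kw_mass <- lapply(split(physiology, physiology$activity), function(d) {
    kruskal_conover(d$mass, d$habitat)
  })
  kw_df <- do.call(rbind, lapply(names(kw_mass), function(a) {
    data.frame(activity = a, H = kw_mass[[a]]$H, df = kw_mass[[a]]$df,
               P = kw_mass[[a]]$P)
  }))
  corr <- correlate_physiology(physiology)

  # --- outputs --------------------------------------------------------------
  files <- c(
    individual_physiology = write_stage_csv(physiology, file.path(out_dir, "individual_physiology.csv"), config, "physiology"),
    species_mechanism = write_stage_csv(mech, file.path(out_dir, "species_mechanism.csv"), config, "mechanism"),
    indval = write_stage_csv(as.data.frame(iv), file.path(out_dir, "indval.csv"), config, "indval"),
    activity = write_stage_csv(activity, file.path(out_dir, "activity.csv"), config, "activity"),
    diel_summary = write_stage_csv(diel, file.path(out_dir, "diel_summary.csv"), config, "microclimate"),
    anova = write_stage_csv(aov3, file.path(out_dir, "anova.csv"), config, "anova"),
    contrasts = write_stage_csv(contr, file.path(out_dir, "contrasts.csv"), config, "contrasts"))

  report <- file.path(out_dir, "report.txt")
  con <- file(report, "w")
  writeLines(sprintf("thermoniche run | seed=%s | config=%s", seed,
                     config_hash(config)), con)
  writeLines(sprintf("species: %d, individuals analysed: %d",
                     length(pool), nrow(physiology)), con)
  best_iv <- as.data.frame(iv)[iv$is_max,
                               c("species", "habitat", "indval", "P_perm",
                                 "category")]
  per_sp <- suppressWarnings(Reduce(
    function(a, b) merge(a, b, by = "species", all.x = TRUE),
    list(stats::aggregate(endothermy ~ species, physiology, mean),
         mech[, c("species", "mechanism")], best_iv,
         activity[, c("species", "call", "source")])))
  utils::capture.output(print(per_sp, digits = 4), file = con)
  writeLines("\ntype-III Wald chi-square (log endothermy):", con)
  utils::capture.output(print(aov3, digits = 4), file = con)
  close(con)

  invisible(list(physiology = physiology, mechanisms = mech, indval = iv,
                 activity = activity, microclimate = diel, lmm = lmm,
                 anova = aov3, contrasts = contr, kw_mass = kw_mass,
                 kw_mass_table = kw_df, correlations = corr,
                 truth = list(community = comm$truth, captures = caps$truth),
                 files = c(files, report = report), out_dir = out_dir))
}

#' Build a run configuration from a YAML file
#'
#' Reads the scalar options of [run_config()] (alpha, permutations, seeds,
#' period boundaries, flight window, capture/sensor lengths) from a YAML
#' mapping; unknown keys are rejected. The species pool itself is code, not
#' config: a `noise_sd` key re-parameterises the bundled default pool.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  opts <- yaml::read_yaml(path)
  pool_noise <- opts$noise_sd
  opts$noise_sd <- NULL
  allowed <- setdiff(names(formals(run_config)), "species_pool")
  bad <- setdiff(names(opts), allowed)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(opts$sensor_amplitudes)) {
    opts$sensor_amplitudes <- unlist(opts$sensor_amplitudes)
  }
  if (!is.null(pool_noise)) {
    opts$species_pool <- default_species_pool(noise_sd = pool_noise)
  }
  do.call(run_config, opts)
}
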