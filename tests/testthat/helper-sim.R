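# Shared small simulated dataset: 6 habitat x activity cells, several species
# per cell, individual-level noise.
sim_analysis_table <- function(n_species_per_cell = 4, n_ind = 5,
                               species_sd = 0, resid_sd = 0.5,
                               cell_effects = NULL, seed = 1) {
  set.seed(seed)
  cells <- expand.grid(habitat = c("native_forest", "agroforestry",
                                   "open_pasture"),
                       activity = c("diurnal", "ENC"),
                       stringsAsFactors = FALSE)
  rows <- list()
  sp_id <- 0
  for (ci in seq_len(nrow(cells))) {
    for (s in seq_len(n_species_per_cell)) {
      sp_id <- sp_id + 1
      eff <- if (is.null(cell_effects)) 0 else cell_effects[ci]
      sp_int <- rnorm(1, 0, species_sd)
      rows[[length(rows) + 1]] <- data.frame(
        species = sprintf("sp%02d", sp_id),
        habitat = cells$habitat[ci], activity = cells$activity[ci],
        mass = rnorm(n_ind, 0.3, 0.05),
        endothermy = exp(1 + eff + sp_int + rnorm(n_ind, 0, resid_sd)))
    }
  }
  do.call(rbind, rows)
}
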