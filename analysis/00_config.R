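# Shared study configuration for the analysis scripts. Sourced by each
# numbered step so every stage regenerates identical inputs from the seed
# instead of passing binary objects around.

library(vectorshift)

study_seed <- 20230810L
results_dir <- "results"

study_config <- landscape_config(
  n_rows = 60, n_cols = 60, cell_size_deg = 2.5 / 60,
  origin_lon = 0, origin_lat = 10, n_gradient_layers = 3,
  noise_sd = 0.5, autocorrelation_range = 3, seed = study_seed)

build_stack <- function() generate_landscape(study_config)

build_climate <- function(stack) {
  generate_monthly_climate(
    study_config, seasonal_amplitude = 9,
    annual_mean_field = 8 + 1.5 * stack$layers$env2,
    prec_pattern = c(1, 1, 2, 3, 4, 6, 8, 7, 5, 3, 2, 1),
    annual_prec = 900, diurnal_half_range = 5)
}

# two virtual species: a mild (A) and a strong (B) introduced-niche shift
study_species <- list(
  A = virtual_species_config(
    native = virtual_niche(c(4.0, 5.0, 5.0), c(1.5, 1.5, 1.5)),
    introduced = virtual_niche(c(5.0, 5.0, 5.0), c(1.5, 1.5, 1.5)),
    n_native = 400, n_introduced = 1500, seed = study_seed + 1L),
  B = virtual_species_config(
    native = virtual_niche(c(4.0, 5.0, 5.0), c(1.5, 1.5, 1.5)),
    introduced = virtual_niche(c(7.0, 5.0, 5.0), c(1.5, 1.5, 1.5)),
    n_native = 400, n_introduced = 1500, seed = study_seed + 2L))

# full-grid background environment (every landscape cell)
background_env <- function(stack) {
  ctr <- grid_centers(stack$grid)
  cells <- expand.grid(r = seq_len(stack$grid$n_rows),
                       c = seq_len(stack$grid$n_cols))
  extract_values(stack, ctr$lon[cells$c], ctr$lat[cells$r])
}
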