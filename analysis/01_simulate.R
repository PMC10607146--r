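#!/usr/bin/env Rscript
# Step 1: simulate the study system.
#
# Builds a synthetic landscape (three environmental gradients with
# spatially autocorrelated noise) and two virtual species with known
# Gaussian niches: species A has a mildly shifted introduced niche
# (1 layer unit), species B a strongly shifted one (3 units). Occurrence
# "archives" are written with the blemishes real archives have (duplicate
# rows, heavy-tailed coordinate uncertainty, shuffled order), so the
# cleaning step has real work to do. True niche parameters and true COUE
# fractions go to truth.json for later parameter-recovery checks.

source("analysis/00_config.R")
suppressPackageStartupMessages(library(jsonlite))

out_dir <- file.path(results_dir, "simulation")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

stack <- build_stack()
message("landscape: ", study_config$n_rows, " x ", study_config$n_cols,
        " cells, ", n_layers(stack), " layers")

archive_blemishes <- function(occ, seed) {
  set.seed(seed)
  # a tenth of the records are exact duplicates; uncertainty is lognormal
  # with a heavy tail, so some records exceed the 5-km filter
  dup <- occ[sample(nrow(occ), round(0.1 * nrow(occ))), ]
  occ <- rbind(occ, dup)
  occ$uncertainty_km <- round(rlnorm(nrow(occ), meanlog = 0, sdlog = 1.1), 2)
  occ$uncertainty_km[sample(nrow(occ), round(0.15 * nrow(occ)))] <- NA
  occ[sample(nrow(occ)), ]
}

truth <- list()
for (sp in names(study_species)) {
  sim <- simulate_virtual_species(stack, study_species[[sp]])
  occ <- archive_blemishes(rbind(sim$native, sim$introduced),
                           seed = study_species[[sp]]$seed + 10L)
  write.csv(occ, file.path(out_dir, paste0("occurrences_", sp, ".csv")),
            row.names = FALSE)
  truth[[sp]] <- list(
    native_mu = study_species[[sp]]$native$mu,
    introduced_mu = study_species[[sp]]$introduced$mu,
    sigma = study_species[[sp]]$native$sigma,
    true_E = sim$truth$E, true_S = sim$truth$S, true_U = sim$truth$U)
  message(sprintf("species %s: %d raw records, true E=%.3f U=%.3f",
                  sp, nrow(occ), sim$truth$E, sim$truth$U))
}

for (nm in names(stack$layers))
  write_layer_csv(stack$layers[[nm]], stack$grid,
                  file.path(out_dir, paste0("layer_", nm, ".csv")))
write_json(list(seed = study_seed, truth = truth),
           file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
message("wrote ", out_dir)
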