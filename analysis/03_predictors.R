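#!/usr/bin/env Rscript
# Step 3: build and select predictors.
#
# Computes the 19 bioclimatic variables from the simulated monthly climate
# and appends the three raw landscape gradients, giving a 22-layer
# candidate stack. A preliminary random-forest suitability model supplies
# permutation importances; collinear pairs (|r| > 0.7, computed at
# presence + background cells) are then pruned worst-first, keeping the
# more important member of each pair. The retained predictor names feed
# the final ensemble models in step 4.

source("analysis/00_config.R")

occ_dir <- file.path(results_dir, "occurrences")
out_dir <- file.path(results_dir, "predictors")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

stack <- build_stack()
clim <- build_climate(stack)
bio <- compute_bioclim(clim)
candidates <- predictor_stack(c(stack$layers, bio$layers), stack$grid)
message("candidate predictors: ", n_layers(candidates))

# modelling cells: presences of species A plus a uniform background draw
occ <- read.csv(file.path(occ_dir, "clean_A.csv"))
set.seed(study_seed + 30L)
bg <- background_env(candidates)
bg_idx <- sample(nrow(bg), 1000)
pres_env <- extract_values(candidates, occ$lon, occ$lat)

# preliminary model for importances: one replicate, one CV repeat
tabs <- sample_pseudo_absences(occ, candidates, replicates = 1,
                               seed = study_seed + 31L)
prelim <- fit_algorithm("RF", tabs[[1]], seed = study_seed + 32L)
imp <- variable_importance(prelim, rbind(pres_env, bg[bg_idx, ]),
                           n_shuffles = 3, seed = study_seed + 33L)
write.csv(data.frame(predictor = names(imp), importance = imp),
          file.path(out_dir, "importance.csv"), row.names = FALSE)

# spatially uniform layers (e.g. precipitation bioclims under a uniform
# rain field) carry no information here; drop them before correlation
cells <- rbind(pres_env, bg[bg_idx, ])
varying <- names(which(vapply(cells, stats::sd, 0) > 1e-12))
message("spatially uniform layers dropped: ",
        paste(setdiff(names(cells), varying), collapse = ", "))
corr <- stats::cor(cells[varying])
keep <- prune_collinear(corr, imp[varying], threshold = 0.7)
writeLines(keep, file.path(out_dir, "retained_predictors.txt"))
message("retained after |r| > 0.7 pruning: ",
        paste(keep, collapse = ", "))
message("wrote ", out_dir)
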