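#!/usr/bin/env Rscript
# Step 4: ensemble suitability models and binary potential ranges.
#
# For each species and population (native / introduced): three
# pseudo-absence replicates, nine algorithms, five 70/30 cross-validation
# repeats. Algorithms passing AUC > 0.8 or TSS > 0.6 enter a TSS-weighted
# ensemble; the continuous ensemble surface is binarized at the maximum
# sensitivity + specificity threshold. A random-forest null-model test
# (19 nulls) checks that each model beats randomized presences.

source("analysis/00_config.R")

occ_dir <- file.path(results_dir, "occurrences")
pred_dir <- file.path(results_dir, "predictors")
out_dir <- file.path(results_dir, "sdm")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

stack <- build_stack()
clim <- build_climate(stack)
bio <- compute_bioclim(clim)
all_layers <- c(stack$layers, bio$layers)
keep <- readLines(file.path(pred_dir, "retained_predictors.txt"))
predictors <- predictor_stack(all_layers[keep], stack$grid)
message("modelling with predictors: ", paste(keep, collapse = ", "))

algs <- sdm_algorithms()
dom_env <- background_env(predictors)
eval_rows <- list()
threshold_rows <- list()

for (sp in names(study_species)) {
  occ <- read.csv(file.path(occ_dir, paste0("clean_", sp, ".csv")))
  for (pop in c("native", "introduced")) {
    pres <- occ[occ$population == pop, ]
    tabs <- sample_pseudo_absences(pres, predictors, replicates = 3,
                                   seed = study_seed + 40L)
    ev <- cross_validate(tabs, algs, repeats = 5,
                         seed = study_seed + 41L)
    ev$species <- sp; ev$population <- pop
    eval_rows[[paste(sp, pop)]] <- ev
    models <- setNames(lapply(algs, function(a)
      fit_algorithm(a, tabs[[1]], seed = study_seed + 42L)), algs)
    ens <- build_ensemble(models, ev)
    surface <- predict_surface(ens, predictors)
    train_scores <- predict_suitability(ens, tabs[[1]])
    th <- max_sens_spec_threshold(train_scores, tabs[[1]]$label)
    binary <- surface >= th
    write_layer_csv(surface * 1, predictors$grid,
                    file.path(out_dir, sprintf("suitability_%s_%s.csv",
                                               sp, pop)))
    write_layer_csv(binary * 1, predictors$grid,
                    file.path(out_dir, sprintf("range_%s_%s.csv", sp, pop)))

    # null-model check on a 70/30 split with a flexible learner
    pres_env <- extract_values(predictors, pres$lon, pres$lat)
    abs_env <- tabs[[1]][tabs[[1]]$label == 0, keep]
    set.seed(study_seed + 43L)
    idx <- sample(nrow(pres_env), round(0.7 * nrow(pres_env)))
    aidx <- sample(nrow(abs_env), round(0.7 * nrow(abs_env)))
    m <- fit_algorithm("RF", rbind(cbind(pres_env[idx, ], label = 1),
                                   cbind(abs_env[aidx, ], label = 0)),
                       seed = study_seed + 44L)
    test <- rbind(cbind(pres_env[-idx, ], label = 1),
                  cbind(abs_env[-aidx, ], label = 0))
    real_auc <- auc_mw(predict_suitability(m, test), test$label)
    nt <- null_model_test(real_auc, pres_env, abs_env, dom_env,
                          algorithm = "RF", n_null = 19,
                          seed = study_seed + 45L)
    threshold_rows[[paste(sp, pop)]] <- data.frame(
      species = sp, population = pop, threshold = th,
      included = sum(ens$weights > 0),
      mean_AUC = mean(ens$evaluations$AUC),
      mean_TSS = mean(ens$evaluations$TSS),
      null_p = nt$p)
    message(sprintf(
      "%s/%s: %d members (of %d), threshold %.3f, null p = %.3f",
      sp, pop, sum(ens$weights > 0), length(algs), th, nt$p))
  }
}

write.csv(do.call(rbind, eval_rows),
          file.path(out_dir, "evaluations.csv"), row.names = FALSE)
write.csv(do.call(rbind, threshold_rows),
          file.path(out_dir, "ensembles.csv"), row.names = FALSE)
message("wrote ", out_dir)
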