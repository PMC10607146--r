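#!/usr/bin/env Rscript
# Step 2: clean the occurrence archives.
#
# For each species: parse the raw CSV, deduplicate, drop records with
# coordinate uncertainty over 5 km (records with missing uncertainty are
# retained), then spatially rarefy at a 5-km radius, per population. The
# retained record counts are the sample sizes all later stages use.

source("analysis/00_config.R")

in_dir <- file.path(results_dir, "simulation")
out_dir <- file.path(results_dir, "occurrences")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

counts <- list()
for (sp in names(study_species)) {
  raw <- load_occurrences(file.path(in_dir,
                                    paste0("occurrences_", sp, ".csv")))
  clean <- clean_occurrences(raw, max_km = 5, radius_km = 5,
                             seed = study_seed + 20L)
  write.csv(clean, file.path(out_dir, paste0("clean_", sp, ".csv")),
            row.names = FALSE)
  tab <- table(clean$population)
  counts[[sp]] <- c(raw = nrow(raw), clean = nrow(clean),
                    native = unname(tab["native"]),
                    introduced = unname(tab["introduced"]))
  message(sprintf(
    "species %s: %d raw -> %d clean (%d native, %d introduced)",
    sp, nrow(raw), nrow(clean), tab["native"], tab["introduced"]))
}
write.csv(do.call(rbind, counts), file.path(out_dir, "counts.csv"))
message("wrote ", out_dir)
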