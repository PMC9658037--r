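#!/usr/bin/env Rscript
# Stage 1 — simulate the trial.
#
# Generates a 36-genotype x 3-replicate x 18-trait replicated trial whose
# genotypic covariance follows a 5-factor structure (blocks of 4/4/4/3/3
# traits, primary loading 0.9, entry-mean h2 = 0.85), with replicate-level
# fixed effects. Writes the long-format phenotype CSV, the trait
# specification, and the simulation truth for later recovery checks.

library(faiselect)

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

cfg <- sim_config(seed = 2026L)
sim <- simulate_trial(cfg)

write_phenotypes(sim$phenotypes, file.path(out_dir, "phenotypes.csv"))
write.csv(as.data.frame(sim$traits), file.path(out_dir, "trait_specs.csv"),
          row.names = FALSE, quote = FALSE)
jsonlite::write_json(
  list(seed = cfg$seed,
       sigma2_a = as.list(sim$truth$sigma2_a),
       sigma2_e = as.list(sim$truth$sigma2_e),
       h2 = as.list(sim$truth$h2),
       genotype_effects = as.data.frame(sim$truth$genotype_effects),
       loadings = as.data.frame(sim$truth$loadings)),
  file.path(out_dir, "simulation_truth.json"),
  auto_unbox = TRUE, digits = NA)

n_plots <- nrow(unique(sim$phenotypes[, c("genotype", "replicate")]))
cat(sprintf(
  "Simulated %d plots (%d genotypes x %d replicates), %d traits.\n",
  n_plots, cfg$n_genotypes, cfg$n_replicates, cfg$n_traits))
cat(sprintf("Per-trait genotypic CV %.0f%%, entry-mean h2 = %.2f.\n",
            100 * cfg$genotypic_cv, cfg$heritabilities[1]))
cat("Wrote phenotypes.csv, trait_specs.csv, simulation_truth.json\n")
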