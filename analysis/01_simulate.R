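#!/usr/bin/env Rscript
# Generate the synthetic sister-cell lineage-tracing experiment that the
# rest of the analysis consumes: a treatment arm and a DMSO-like control
# arm, each with a profiled pre-treatment sample and a post-treatment
# survivor sample, plus ground truth (barcode library, latent resistance /
# fitness scores, planted gene programs).

suppressMessages(library(resistrace))

outdir <- "results/simulation"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(n_lineages = 1500, n_genes = 2000,
                  n_resistance_genes = 200, resistance_effect = 0.5,
                  n_fitness_genes = 200, kill_fraction = 0.70,
                  heritability = 0.6, seed = 42)
sim <- simulate_experiment(cfg)

for (s in c("pre", "post", "control_pre", "control_post")) {
  write_cell_matrix(sim[[s]], file.path(outdir, s), format = "mtx")
}
write_ground_truth(sim$truth, file.path(outdir, "ground_truth.json"))
jsonlite::write_json(unclass(cfg), file.path(outdir, "config.json"),
                     auto_unbox = TRUE)

cat(sprintf(
  "simulated %d lineages/arm, %d genes\n  pre: %d cells  post: %d survivors (realized kill %.1f%%)\n  control pre: %d cells  control post: %d survivors\n",
  cfg$n_lineages, cfg$n_genes, ncol(sim$pre), ncol(sim$post),
  100 * sim$truth$realized_kill_treatment,
  ncol(sim$control_pre), ncol(sim$control_post)))
cat("wrote", outdir, "\n")
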