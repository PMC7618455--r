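#!/usr/bin/env Rscript
# Fate stage: match pre-treatment lineage labels against the post-treatment
# survivor samples to annotate pre-resistant / pre-sensitive cells in the
# treatment arm and pre-fit / pre-unfit cells in the control arm; enumerate
# sister pairs and singleton-lineage cells.

suppressMessages(library(resistrace))

simdir <- "results/simulation"
outdir <- "results/fates"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

labels <- read_label_map("results/barcodes/cell_labels.tsv")
post <- read_cell_matrix(file.path(simdir, "post"))
cpre <- read_cell_matrix(file.path(simdir, "control_pre"))
cpost <- read_cell_matrix(file.path(simdir, "control_post"))
clabels <- setNames(cpre$label, cpre$cell_id)

fates <- assign_fates(labels, post$label, arm = "treatment")
cfates <- assign_fates(clabels, cpost$label, arm = "control")

write.table(fates$cells, file.path(outdir, "fates_treatment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cfates$cells, file.path(outdir, "fates_control.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

pairs <- sister_pairs(labels)
write.table(pairs, file.path(outdir, "sister_pairs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(singleton_cells(labels), file.path(outdir, "singleton_cells.txt"))

lin <- fates$lineages
cat(sprintf(
  "treatment arm: %d pre-resistant / %d pre-sensitive lineages (%d / %d cells)\n",
  sum(lin$fate == "pre_resistant"), sum(lin$fate == "pre_sensitive"),
  sum(fates$cells$fate == "pre_resistant"),
  sum(fates$cells$fate == "pre_sensitive")))
cat(sprintf("control arm: %d pre-fit / %d pre-unfit lineages\n",
            sum(cfates$lineages$fate == "pre_fit"),
            sum(cfates$lineages$fate == "pre_unfit")))
cat(sprintf("sister pairs (two-cell lineages): %d  singleton cells: %d\n",
            nrow(pairs), length(singleton_cells(labels))))
cat("wrote", outdir, "\n")
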