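#!/usr/bin/env Rscript
# Sister-similarity stage: QC + log-normalize the pre-treatment matrix,
# compare sister-pair distances with random-pair distances on the top 1000
# variable genes, and derive the sister-concordant gene set (genes whose
# within-pair fold change is significantly smaller between sisters).

suppressMessages(library(resistrace))

outdir <- "results/sisters"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

pre <- read_cell_matrix("results/simulation/pre")
pre <- filter_genes(pre, min_cells = 3)
pre <- normalize_log(pre)
labels <- read_label_map("results/barcodes/cell_labels.tsv")
labels <- labels[intersect(names(labels), pre$cell_id)]

pairs <- sister_pairs(labels)
top <- top_variable_genes(pre, 1000)
m_top <- lognorm_matrix(pre, top)
pd <- pair_distances(m_top, pairs, n_random = 100000, seed = 44)
write.table(pd, file.path(outdir, "pair_distances.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

sis <- pd$distance[pd$type == "sister"]
rnd <- pd$distance[pd$type == "random"]
tt <- t.test(rnd, sis, alternative = "greater")
cat(sprintf(
  "distances on top 1000 variable genes: %d sister pairs, %d random pairs\n  mean sister %.2f < mean random %.2f (one-sided P = %.3g)\n",
  length(sis), length(rnd), mean(sis), mean(rnd), tt$p.value))

# concordant genes on the full (low-expression-filtered) gene set
m <- lognorm_matrix(pre)
keep <- filter_low_expression_genes(m, quantile = 0.10)
cat(sprintf("low-expression filter: removed %d genes (cutoff %.3f)\n",
            nrow(m) - length(keep), attr(keep, "cutoff")))
pd_all <- pair_distances(m[keep, ], pairs, n_random = 20000, seed = 45)
sis_kept <- filter_distant_sisters(pd_all, quantile = 0.90)
cat(sprintf("distant-sister filter: kept %d of %d pairs (cutoff %.2f)\n",
            nrow(sis_kept), nrow(pairs), attr(sis_kept, "cutoff")))

conc <- sister_concordant_genes(m[keep, ], sis_kept,
                                pd_all[pd_all$type == "random", ])
write.table(conc, file.path(outdir, "concordance.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("sister-concordant genes at FDR 0.05: %d of %d tested\n",
            sum(conc$concordant), nrow(conc)))
cat("wrote", outdir, "\n")
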