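#!/usr/bin/env Rscript
# Signature stage: Wilcoxon rank-sum differential expression between
# pre-resistant and pre-sensitive singleton-lineage cells (and pre-fit vs
# pre-unfit in the control arm), bootstrap/permutation specificity contrast,
# and assembly of the four signature variants restricted to
# sister-concordant genes.

suppressMessages(library(resistrace))

outdir <- "results/signatures"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

prep <- function(dir) {
  x <- read_cell_matrix(dir)
  normalize_log(filter_genes(x, 3))
}
pre <- prep("results/simulation/pre")
cpre <- prep("results/simulation/control_pre")

fates <- read.delim("results/fates/fates_treatment.tsv")
cfates <- read.delim("results/fates/fates_control.tsv")
singles <- readLines("results/fates/singleton_cells.txt")
csingles <- singleton_cells(setNames(cpre$label, cpre$cell_id))

grp <- function(df, cls, ss) intersect(df$cell_id[df$fate == cls], ss)
m <- lognorm_matrix(pre)
mc <- lognorm_matrix(cpre)
res <- grp(fates, "pre_resistant", singles)
sen <- grp(fates, "pre_sensitive", singles)
fit <- grp(cfates, "pre_fit", csingles)
unf <- grp(cfates, "pre_unfit", csingles)
cat(sprintf("groups (singleton cells): %d pre-resistant vs %d pre-sensitive; %d pre-fit vs %d pre-unfit\n",
            length(res), length(sen), length(fit), length(unf)))

sig <- differential_expression(m, res, sen)
fsig <- differential_expression(mc, fit, unf)
spec <- specificity_test(m, res, sen, mc, fit, unf,
                         n_boot = 1000, n_perm = 1000, seed = 46,
                         signature = sig)

write.table(sig, file.path(outdir, "pre_resistance_signature.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(fsig, file.path(outdir, "pre_fitness_signature.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(spec, file.path(outdir, "specificity.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("signature genes at adjusted P < 0.05: %d up / %d down\n",
            sum(sig$padj < 0.05 & sig$log2fc > 0),
            sum(sig$padj < 0.05 & sig$log2fc < 0)))
cat(sprintf("specifically up-regulated in pre-resistant cells: %d genes\n",
            sum(spec$specific)))

conc <- read.delim("results/sisters/concordance.tsv")
variants <- build_signature_variants(sig, fsig, spec,
                                     conc$gene[conc$concordant])
jsonlite::write_json(lapply(variants, as.list),
                     file.path(outdir, "signature_variants.json"),
                     auto_unbox = TRUE, digits = NA)
cat("variant sizes:",
    paste(sprintf("%s=%d", names(variants), lengths(variants)),
          collapse = "  "), "\n")
cat("wrote", outdir, "\n")
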