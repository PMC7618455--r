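# shared small simulated experiment with a planted resistance program
sig_sim <- function(seed = 51, effect = 0.8) {
  cfg <- sim_config(n_lineages = 500, n_genes = 300, mean_depth = 6000,
                    n_resistance_genes = 40, n_fitness_genes = 40,
                    resistance_effect = effect, seed = seed)
  sim <- simulate_experiment(cfg)
  pre <- normalize_log(sim$pre)
  cpre <- normalize_log(sim$control_pre)
  labs <- setNames(pre$label, pre$cell_id)
  clabs <- setNames(cpre$label, cpre$cell_id)
  fates <- assign_fates(labs, sim$post$label, "treatment")
  cfates <- assign_fates(clabs, sim$control_post$label, "control")
  grp <- function(fp, cls, singles) {
    intersect(fp$cells$cell_id[fp$cells$fate == cls], singles)
  }
  singles <- singleton_cells(labs)
  csingles <- singleton_cells(clabs)
  list(sim = sim,
       m_treat = lognorm_matrix(pre), m_ctrl = lognorm_matrix(cpre),
       res = grp(fates, "pre_resistant", singles),
       sens = grp(fates, "pre_sensitive", singles),
       fit = grp(cfates, "pre_fit", csingles),
       unfit = grp(cfates, "pre_unfit", csingles))
}

test_that("wilcoxon P-values match exact enumeration on tiny instances", {
  # tie-free 5v5 instances with interleaved groups; at this size the
  # tie-corrected normal approximation tracks the exact null within 10%
  # away from the extreme tail
  m <- rbind(
    G1 = c(3, 5, 7, 9, 12, 14, 18, 20, 25, 30),
    G2 = c(30, 5, 25, 9, 18, 12, 14, 3, 7, 41),
    G3 = c(2, 2, 3, 3, 2, 3, 2, 3, 3, 2))     # heavy ties
  colnames(m) <- paste0("c", 1:10)
  a <- paste0("c", c(1, 3, 5, 7, 9))
  b <- paste0("c", c(2, 4, 6, 8, 10))
  sig <- differential_expression(m, a, b)
  for (g in 1:2) {   # tie-free rows: exact enumeration oracle
    p_exact <- exact_ranksum_p(m[g, a], m[g, b])
    expect_lt(abs(sig$p[g] - p_exact) / p_exact, 0.10)
  }
  # tied row: agrees with the reference tie-corrected approximation
  ref <- suppressWarnings(wilcox.test(m[3, a], m[3, b], exact = FALSE,
                                      correct = TRUE)$p.value)
  expect_equal(sig$p[3], ref, tolerance = 1e-9)
})

test_that("null differential expression yields uniform P-values", {
  cfg <- sim_config(n_lineages = 400, n_genes = 2000, mean_depth = 15000,
                    n_resistance_genes = 0, n_fitness_genes = 0, seed = 61)
  sim <- simulate_experiment(cfg)
  pre <- normalize_log(sim$pre)
  m <- lognorm_matrix(pre)
  keep <- rowSums(as.matrix(SummarizedExperiment::assay(sim$pre, "counts")) > 0) >= 3
  m <- m[keep, ]
  set.seed(62)
  cells <- sample(colnames(m))
  a <- cells[1:150]
  b <- cells[151:300]
  sig <- differential_expression(m, a, b)
  ks <- suppressWarnings(ks.test(sig$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  # adjusted P never below raw P
  expect_true(all(sig$padj >= sig$p - 1e-12))
})

test_that("a planted two-fold shift is recovered with the right sign", {
  set.seed(71)
  n <- 200
  base <- matrix(rpois(100 * 2 * n, lambda = 20), nrow = 100)
  base[1, seq_len(n)] <- rpois(n, 40)    # true 2-fold up in group A
  colnames(base) <- paste0("c", seq_len(2 * n))
  rownames(base) <- paste0("G", 1:100)
  sce <- normalize_log(make_test_sce(base))
  m <- lognorm_matrix(sce)
  sig <- differential_expression(m, paste0("c", 1:n),
                                 paste0("c", n + 1:n))
  expect_gt(sig$log2fc[1], 0.7)
  expect_lt(sig$log2fc[1], 1.3)
  expect_lt(sig$padj[1], 0.05)

  expect_error(differential_expression(m, c("c1", "c2"), c("c3", "c4", "c5")),
               "three cells")
  expect_error(differential_expression(m, c("c1", "c2", "c3"),
                                       c("c3", "c4", "c5")), "disjoint")
})

test_that("specificity testing separates resistance-only from shared effects", {
  s <- sig_sim()
  sig <- differential_expression(s$m_treat, s$res, s$sens)
  spec <- suppressWarnings(specificity_test(
    s$m_treat, s$res, s$sens, s$m_ctrl, s$fit, s$unfit,
    n_boot = 300, n_perm = 300, seed = 5, signature = sig))

  truth <- s$sim$truth
  res_genes <- truth$resistance_genes
  fit_genes <- truth$fitness_genes

  # resistance genes carry positive delta on average, fitness genes do not
  expect_gt(mean(spec$delta_log2fc[spec$gene %in% res_genes]),
            mean(spec$delta_log2fc[spec$gene %in% fit_genes]))
  # the specific set is dominated by true resistance genes
  hits <- spec$gene[spec$specific]
  expect_gt(length(hits), 0)
  expect_lte(mean(hits %in% fit_genes), 0.10)

  # determinism under a fixed seed
  spec2 <- suppressWarnings(specificity_test(
    s$m_treat, s$res, s$sens, s$m_ctrl, s$fit, s$unfit,
    n_boot = 300, n_perm = 300, seed = 5, signature = sig))
  expect_identical(spec, spec2)
})

test_that("zero-variance genes get delta 0 and P 1", {
  m <- rbind(G1 = rep(1.5, 12), G2 = c(rnorm(12)))
  colnames(m) <- paste0("c", 1:12)
  spec <- suppressWarnings(specificity_test(
    m, paste0("c", 1:3), paste0("c", 4:6),
    m, paste0("c", 7:9), paste0("c", 10:12),
    n_boot = 100, n_perm = 100, seed = 1))
  expect_equal(spec$delta_log2fc[spec$gene == "G1"], 0)
  expect_equal(spec$p_boot[spec$gene == "G1"], 1)
  expect_equal(spec$p_perm[spec$gene == "G1"], 1)
})

test_that("signature variants nest correctly and honor the concordant set", {
  genes <- paste0("G", 1:10)
  res_sig <- structure(
    data.frame(gene = genes, log2fc = seq(-1, 1, length.out = 10),
               p = c(0.01, 0.2, 0.03, 0.6, 0.02, 0.04, 0.5, 0.01, 0.9, 0.02),
               padj = 0.1, pct_a = 1, pct_b = 1),
    class = c("gene_signature", "data.frame"))
  fit_sig <- res_sig
  fit_sig$log2fc <- 0
  spec <- data.frame(gene = genes,
                     delta_log2fc = res_sig$log2fc,
                     p_boot = c(0.01, 0.04, 0.2, 0.3, 0.01, 0.6, 0.01,
                                0.02, 0.7, 0.04))
  concordant <- paste0("G", 1:8)          # G9, G10 not concordant

  v <- build_signature_variants(res_sig, fit_sig, spec, concordant)
  # non-concordant genes absent from all four variants
  expect_false(any(c("G9", "G10") %in% unlist(lapply(v, names))))
  # variant 2 restricted to wilcoxon P < 0.05, subset of variant 1
  expect_true(all(names(v$wilcox_filtered) %in% names(v$full)))
  expect_false("G2" %in% names(v$wilcox_filtered))   # P = 0.2
  expect_true("G1" %in% names(v$wilcox_filtered))    # P = 0.01
  # variant 4 subset of variant 3
  expect_true(all(names(v$contrast_boot_filtered) %in% names(v$contrast)))
  # with a flat fitness signature, the contrast equals the resistance log2FC
  expect_equal(v$contrast[names(v$full)], v$full, tolerance = 1e-12)

  # an empty variant is an error naming the variant
  spec_none <- spec
  spec_none$p_boot <- 1
  expect_error(build_signature_variants(res_sig, fit_sig, spec_none,
                                        concordant),
               "contrast_boot_filtered")
})

test_that("fully permuted fates produce few specific genes", {
  s <- sig_sim(seed = 81)
  set.seed(82)
  all_t <- sample(c(s$res, s$sens))
  all_c <- sample(c(s$fit, s$unfit))
  res_p <- all_t[seq_along(s$res)]
  sens_p <- setdiff(all_t, res_p)
  fit_p <- all_c[seq_along(s$fit)]
  unfit_p <- setdiff(all_c, fit_p)
  sig_p <- differential_expression(s$m_treat, res_p, sens_p)
  spec_p <- suppressWarnings(specificity_test(
    s$m_treat, res_p, sens_p, s$m_ctrl, fit_p, unfit_p,
    n_boot = 200, n_perm = 200, seed = 83, signature = sig_p))
  expect_lte(sum(spec_p$specific), 0.05 * nrow(spec_p) + 2)
})
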