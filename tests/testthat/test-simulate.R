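small_cfg <- function(...) {
  args <- list(...)
  defaults <- list(n_lineages = 150L, n_genes = 250L, mean_depth = 4000,
                   n_resistance_genes = 25L, n_fitness_genes = 25L, seed = 3L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

test_that("config invariants are enforced", {
  expect_error(sim_config(n_genes = 100, n_resistance_genes = 60,
                          n_fitness_genes = 60), "exceed")
  expect_error(sim_config(heritability = 1.2), "\\[0,1\\]")
  expect_error(sim_config(heritability = c(0.5, 0.5)), "length n_genes")
  expect_warning(small_cfg(kill_fraction = 0), "degenerate")
})

test_that("barcode libraries are unique 20-mers over ACGT and deterministic", {
  one <- generate_barcode_library(1, seed = 0)
  expect_match(one, "^[ACGT]{20}$")
  many <- generate_barcode_library(1000, seed = 7)
  expect_length(unique(many), 1000)
  expect_true(all(grepl("^[ACGT]{20}$", many)))
  expect_identical(generate_barcode_library(3, seed = 5),
                   generate_barcode_library(3, seed = 5))
  expect_error(generate_barcode_library(5, label_length = 1), "distinct labels")
})

test_that("the experiment generator is deterministic and conserves labels", {
  cfg <- small_cfg()
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(
    as.matrix(SummarizedExperiment::assay(a$pre, "counts")),
    as.matrix(SummarizedExperiment::assay(b$pre, "counts")))
  expect_identical(a$truth$lineages_treatment, b$truth$lineages_treatment)

  # every post-treatment cell's label exists in the ground-truth library,
  # and every surviving lineage's label appears in the post output
  expect_true(all(a$post$label %in% a$truth$labels))
  surv <- a$truth$lineages_treatment$survived
  expect_setequal(a$truth$lineages_treatment$label[surv],
                  unique(a$post$label))

  # each lineage contributes exactly two daughters
  lt <- a$truth$lineages_treatment
  expect_true(all(lt$n_pre_cells + lt$n_treated_cells == 2L))

  # resistance scores are standard normal before effect scaling
  expect_lt(abs(mean(lt$resistance_score)), 0.2)
  expect_lt(abs(sd(lt$resistance_score) - 1), 0.2)
})

test_that("treated-cell death rate is calibrated to the kill fraction", {
  cfg <- sim_config(n_lineages = 2000, n_genes = 60, mean_depth = 600,
                    n_resistance_genes = 10, n_fitness_genes = 10,
                    kill_fraction = 0.70, seed = 11)
  sim <- simulate_experiment(cfg)
  expect_gte(sim$truth$realized_kill_treatment, 0.65)
  expect_lte(sim$truth$realized_kill_treatment, 0.75)
})

test_that("ground-truth resistance genes are enriched in surviving lineages", {
  cfg <- small_cfg(resistance_effect = 0.8, seed = 21)
  sim <- simulate_experiment(cfg)
  pre <- normalize_log(sim$pre)
  m <- lognorm_matrix(pre)
  lt <- sim$truth$lineages_treatment
  surv_labels <- lt$label[lt$survived]
  res_cells <- pre$cell_id[pre$label %in% surv_labels]
  sens_cells <- setdiff(pre$cell_id, res_cells)
  res_genes <- sim$truth$resistance_genes
  expect_gt(mean(m[res_genes, res_cells]), mean(m[res_genes, sens_cells]))
})

test_that("sister similarity strengthens monotonically with heritability", {
  mean_sister_dist <- function(h) {
    cfg <- small_cfg(heritability = h, resistance_effect = 0,
                     fitness_effect = 0, seed = 31)
    sim <- simulate_experiment(cfg)
    pre <- normalize_log(sim$pre)
    labs <- setNames(pre$label, pre$cell_id)
    sp <- sister_pairs(labs)
    m <- lognorm_matrix(pre, top_variable_genes(pre, 100))
    pd <- pair_distances(m, sp, n_random = 0 + nrow(sp), seed = 1)
    mean(pd$distance[pd$type == "sister"])
  }
  d <- vapply(c(0, 0.45, 0.9), mean_sister_dist, numeric(1))
  expect_true(all(diff(d) < 0))
})

test_that("read corruption follows the per-base substitution model", {
  labs <- setNames(random_labels(500), paste0("c", 1:500))

  # zero error rate: identity after extraction
  clean <- corrupt_reads(labs, reads_per_cell = 2, error_rate = 0, seed = 1)
  expect_identical(extract_label(clean$read),
                   rep(unname(labs), each = 2))

  # closed form: P(>=1 error in 20 bases) = 1 - 0.99^20 at rate 0.01
  noisy <- corrupt_reads(labs, reads_per_cell = 20, error_rate = 0.01,
                         seed = 2)
  got <- extract_label(noisy$read)
  frac_err <- mean(got != rep(unname(labs), each = 20))
  expect_lt(abs(frac_err - (1 - 0.99^20)), 0.03)

  # determinism
  again <- corrupt_reads(labs, reads_per_cell = 20, error_rate = 0.01,
                         seed = 2)
  expect_identical(noisy, again)

  expect_error(corrupt_reads(labs, error_rate = 0.5), "0.25")
})

test_that("dose-response surfaces honor their generating null model", {
  doses <- c(0.1, 0.5, 1, 5, 10)

  # bliss null, no synergy, no noise: bliss excess identically 0
  drm <- simulate_dose_response("bliss-null", doses, doses,
                                synergy_delta = 0, noise_sd = 0,
                                replicates = 1, seed = 1)
  ex <- bliss_excess(to_inhibition(drm))
  expect_lt(max(abs(ex$excess), na.rm = TRUE), 1e-9)

  # planted shift moves the mean bliss score by that amount
  drm10 <- simulate_dose_response("bliss-null", doses, doses,
                                  synergy_delta = 10, noise_sd = 0,
                                  replicates = 1, seed = 1)
  expect_equal(bliss_excess(to_inhibition(drm10))$mean, 10, tolerance = 1e-9)

  # hsa null with noise: mean hsa score centred near 0 across sims
  hsa_means <- vapply(1:25, function(s) {
    d <- simulate_dose_response("hsa-null", doses, doses, synergy_delta = 0,
                                noise_sd = 2, replicates = 3, seed = s)
    hsa_excess(to_inhibition(d))$mean
  }, numeric(1))
  expect_lt(abs(mean(hsa_means)), 2)

  expect_error(simulate_dose_response("bliss-null", 1, doses), "nonzero doses")
  expect_error(simulate_dose_response("bliss-null", doses, doses,
                                      noise_sd = -1), "non-negative")
})
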