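# build a dose_response_matrix directly from a known inhibition surface
drm_from_inh <- function(inh, doses1, doses2, replicates = 1) {
  readings <- array(rep(100 - inh, replicates),
                    dim = c(length(doses1), length(doses2), replicates))
  dose_response_matrix(doses1, doses2, readings, neg_ctrl = 100, pos_ctrl = 0)
}

test_that("control anchoring maps readings linearly to percent inhibition", {
  d <- c(0, 1, 2)
  readings <- array(100, c(3, 3, 1))
  readings[2, 1, 1] <- 0     # equals positive (total-kill) control
  readings[3, 1, 1] <- 50    # midway
  drm <- dose_response_matrix(d, d, readings, neg_ctrl = 100, pos_ctrl = 0)
  inh <- to_inhibition(drm)
  expect_equal(inh[1, 1], 0)       # reading = negative control
  expect_equal(inh[2, 1], 100)     # reading = positive control
  expect_equal(inh[3, 1], 50)      # linear in between

  expect_error(dose_response_matrix(d, d, readings, neg_ctrl = 0,
                                    pos_ctrl = 100), "control")
  expect_error(dose_response_matrix(c(1, 2, 3), d, readings, 100, 0),
               "include 0")
  expect_error(dose_response_matrix(c(0, 2, 1), d, readings, 100, 0),
               "increasing")
})

test_that("HSA and Bliss excess match their closed forms", {
  doses <- c(0, 1)
  # monotherapies 20% and 30%, combo 50%: HSA excess 20
  inh <- matrix(c(0, 20, 30, 50), 2, 2)       # rows drug1, cols drug2
  hsa <- hsa_excess(inh)
  expect_equal(hsa$mean, 20)
  # combo equal to the better monotherapy: excess 0
  expect_equal(hsa_excess(matrix(c(0, 20, 30, 30), 2, 2))$mean, 0)
  # combo below both: negative
  expect_lt(hsa_excess(matrix(c(0, 20, 30, 10), 2, 2))$mean, 0)

  # Bliss: 0.2 + 0.3 - 0.06 = 0.44 -> excess 0 at 44%
  expect_equal(bliss_excess(matrix(c(0, 20, 30, 44), 2, 2))$mean, 0)
  # 54% -> +10
  expect_equal(bliss_excess(matrix(c(0, 20, 30, 54), 2, 2))$mean, 10)
  # an absorbing monotherapy at 100%: expected 100
  expect_equal(bliss_excess(matrix(c(0, 100, 30, 90), 2, 2))$mean, -10)

  # Bliss expected >= HSA expected pointwise, hence excess ordering flips
  set.seed(3)
  m <- matrix(c(0, runif(3, 10, 90), runif(12, 0, 100)), 4, 4)
  m[1, ] <- c(0, runif(3, 10, 90))
  expect_true(all(bliss_excess(m)$excess <= hsa_excess(m)$excess + 1e-9,
                  na.rm = TRUE))
})

test_that("4PL fitting recovers generating parameters on clean curves", {
  d <- c(0, 0.1, 0.5, 1, 5, 10, 50)
  truth <- c(ymin = 0, ymax = 85, ec50 = 2, slope = 1.4)
  y <- four_pl(d, truth[1], truth[2], truth[3], truth[4])
  fit <- fit_4pl(d, y)
  expect_equal(unname(fit["ymax"]), 85, tolerance = 0.05 * 85)
  expect_equal(unname(fit["ec50"]), 2, tolerance = 0.05 * 2)
  expect_equal(unname(fit["slope"]), 1.4, tolerance = 0.05 * 1.4)
  expect_error(fit_4pl(c(0, 1, 2), c(0, 10, 20)), "three nonzero")
})

test_that("Loewe excess vanishes on dose-additive surfaces (sham combination)", {
  # a drug combined with itself: observed combo = monotherapy at d1 + d2
  par <- c(ymin = 0, ymax = 90, ec50 = 2, slope = 1.3)
  doses <- c(0, 0.25, 0.5, 1, 2, 4)
  inh <- outer(doses, doses, function(a, b)
    four_pl(a + b, par[1], par[2], par[3], par[4]))
  dimnames(inh) <- list(d1 = doses, d2 = doses)
  lw <- loewe_excess(inh)
  expect_lt(abs(lw$mean), 1)

  # planted super-additive shift is recovered
  inh10 <- inh
  inh10[-1, -1] <- inh10[-1, -1] + 10
  lw10 <- loewe_excess(inh10)
  expect_gte(lw10$mean, 8)
  expect_lte(lw10$mean, 12)
})

test_that("ZIP delta vanishes on its own null and sees planted shifts", {
  p1 <- c(0, 90, 1, 1.5)
  p2 <- c(0, 80, 5, 1.2)
  d1 <- c(0, 0.2, 0.5, 1, 2, 5)
  d2 <- c(0, 1, 2.5, 5, 10, 25)
  y1 <- four_pl(d1, p1[1], p1[2], p1[3], p1[4])
  y2 <- four_pl(d2, p2[1], p2[2], p2[3], p2[4])
  inh <- 100 * outer(y1 / 100, y2 / 100, function(a, b) a + b - a * b)
  dimnames(inh) <- list(d1 = d1, d2 = d2)
  z <- zip_excess(inh)
  expect_lt(abs(z$mean), 1)

  inh10 <- inh
  inh10[-1, -1] <- inh10[-1, -1] + 10
  z10 <- zip_excess(inh10)
  expect_gte(z10$mean, 8)
  expect_lte(z10$mean, 12)

  # flat zero-effect second drug: delta stays near 0
  flat <- 100 * outer(y1 / 100, rep(0, 6), function(a, b) a + b - a * b)
  dimnames(flat) <- list(d1 = d1, d2 = d2)
  expect_lt(abs(zip_excess(flat)$mean), 1)
})

test_that("all four models are null-centred on their own noise-free surfaces", {
  doses <- c(0, 0.3, 1, 3, 10)
  for (model in c("bliss-null", "hsa-null", "additive-shift")) {
    drm <- simulate_dose_response(model, doses, doses, synergy_delta = 0,
                                  noise_sd = 0, replicates = 1, seed = 2)
    inh <- to_inhibition(drm)
    score <- switch(model,
                    "bliss-null" = bliss_excess(inh)$mean,
                    "hsa-null" = hsa_excess(inh)$mean,
                    "additive-shift" = loewe_excess(inh)$mean)
    expect_lt(abs(score), 1)
  }
  # ZIP null = Bliss surface generated from true 4PL monotherapies
  drmz <- simulate_dose_response("bliss-null", doses, doses, synergy_delta = 0,
                                 noise_sd = 0, replicates = 1, seed = 3)
  expect_lt(abs(zip_excess(to_inhibition(drmz))$mean), 1)
})

test_that("synergy scores are invariant to swapping the two drugs", {
  doses1 <- c(0, 0.3, 1, 3, 9)
  doses2 <- c(0, 0.5, 1.5, 5, 15)
  drm <- simulate_dose_response("bliss-null", doses1, doses2,
                                synergy_delta = 7, noise_sd = 0,
                                replicates = 1, seed = 4)
  inh <- to_inhibition(drm)
  inh_t <- t(inh)
  dimnames(inh_t) <- list(d1 = doses2, d2 = doses1)
  for (f in list(hsa_excess, bliss_excess, loewe_excess, zip_excess)) {
    expect_equal(f(inh)$mean, f(inh_t)$mean, tolerance = 1e-6)
  }
})

test_that("the synergistic call uses an inclusive >= 5 boundary", {
  expect_identical(classify_synergy(5.0), "synergistic")
  expect_identical(classify_synergy(4.99), "not")
  expect_identical(classify_synergy(-3), "not")
})

test_that("bootstrap significance behaves at the degenerate extremes", {
  doses <- c(0, 0.3, 1, 3, 10)
  # all replicates identical, strong synergy: P at its minimum 2/(n+1)
  drm <- simulate_dose_response("bliss-null", doses, doses,
                                synergy_delta = 10, noise_sd = 0,
                                replicates = 3, seed = 5)
  bs <- suppressWarnings(bootstrap_significance(drm, "bliss", n_boot = 10,
                                                seed = 6))
  expect_equal(bs$p, 2 / 11)
  expect_equal(bs$observed, 10, tolerance = 1e-9)

  # null surfaces with noise: bootstrap P is not concentrated at small
  # values (a zero true mean keeps bootstrap means straddling zero)
  p0 <- vapply(1:12, function(s) {
    d0 <- simulate_dose_response("bliss-null", doses, doses,
                                 synergy_delta = 0, noise_sd = 2,
                                 replicates = 3, seed = 200 + s)
    suppressWarnings(bootstrap_significance(d0, "bliss", n_boot = 50,
                                            seed = s)$p)
  }, numeric(1))
  expect_gt(mean(p0), 0.4)

  # single-replicate data cannot be bootstrapped
  drm1 <- simulate_dose_response("bliss-null", doses, doses, replicates = 1,
                                 seed = 9)
  expect_error(bootstrap_significance(drm1, "bliss"), "parametric")

  # planted synergy with noise is detected most of the time even at 10 draws
  hits <- vapply(1:20, function(s) {
    d <- simulate_dose_response("bliss-null", doses, doses,
                                synergy_delta = 10, noise_sd = 2,
                                replicates = 3, seed = 100 + s)
    suppressWarnings(bootstrap_significance(d, "bliss", n_boot = 10,
                                            seed = s)$p) < 0.2
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("the orchestrator reports per-model scores, P-values and calls", {
  doses <- c(0, 0.3, 1, 3, 10)
  drm <- simulate_dose_response("bliss-null", doses, doses,
                                synergy_delta = 8, noise_sd = 1,
                                replicates = 3, seed = 11)
  res <- synergy_score(drm, models = c("hsa", "bliss"), n_boot = 10, seed = 12)
  expect_named(res, c("hsa", "bliss"))
  expect_identical(res$bliss$call,
                   classify_synergy(res$bliss$mean))
  expect_gt(res$bliss$mean, 5)
  expect_true(all(is.na(res$bliss$excess[1, ])))   # monotherapy cells masked
})
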