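#' Dose-response combination matrix
#'
#' Container for raw viability readings over a two-drug dose grid (both
#' grids include the zero dose) with plate controls: the negative (growth)
#' control anchors 0% inhibition, the positive (total-kill) control anchors
#' 100%.
#'
#' @param doses1,doses2 strictly increasing dose vectors including 0.
#' @param readings numeric array `[length(doses1), length(doses2),
#'   n_replicates]` of raw viability readings.
#' @param neg_ctrl,pos_ctrl control readings (vectors allowed; means are
#'   used). `mean(neg_ctrl)` must exceed `mean(pos_ctrl)`.
#' @param truth optional noise-free inhibition surface (synthetic data only).
#' @param model optional generating-model tag (synthetic data only).
#' @return object of class `dose_response_matrix`.
#' @export
dose_response_matrix <- function(doses1, doses2, readings,
                                 neg_ctrl, pos_ctrl,
                                 truth = NULL, model = NULL) {
  if (is.matrix(readings)) readings <- array(readings, c(dim(readings), 1L))
  stopifnot(length(dim(readings)) == 3L,
            dim(readings)[1] == length(doses1),
            dim(readings)[2] == length(doses2))
  if (doses1[1] != 0 || doses2[1] != 0) .halt("dose grids must include 0 first")
  if (any(diff(doses1) <= 0) || any(diff(doses2) <= 0)) {
    .halt("doses must be strictly increasing")
  }
  neg <- mean(neg_ctrl); pos <- mean(pos_ctrl)
  if (!is.finite(neg) || !is.finite(pos)) .halt("controls must be finite")
  if (neg <= pos) .halt("negative (growth) control must exceed positive (total-kill) control")
  structure(list(doses1 = doses1, doses2 = doses2, readings = readings,
                 neg_ctrl = neg, pos_ctrl = pos,
                 truth = truth, model = model),
            class = "dose_response_matrix")
}

#' Normalize raw readings to percent inhibition
#'
#' `inhibition% = 100 * (neg - reading) / (neg - pos)`, averaged over
#' replicate layers. Values outside `[0, 100]` are possible on noisy data and
#' are not clipped; an `out_of_range` attribute flags them.
#'
#' @param drm a [dose_response_matrix()].
#' @return matrix (doses1 x doses2) of mean percent inhibition, with dose
#'   dimnames.
#' @export
to_inhibition <- function(drm) {
  stopifnot(inherits(drm, "dose_response_matrix"))
  mean_read <- apply(drm$readings, c(1L, 2L), mean)
  inh <- 100 * (drm$neg_ctrl - mean_read) / (drm$neg_ctrl - drm$pos_ctrl)
  dimnames(inh) <- list(d1 = drm$doses1, d2 = drm$doses2)
  attr(inh, "out_of_range") <- sum(inh < 0 | inh > 100)
  inh
}

# internal: inhibition surface from one bootstrap draw of replicate layers
.inhibition_resampled <- function(drm) {
  dims <- dim(drm$readings)
  nrep <- dims[3]
  mean_read <- matrix(NA_real_, dims[1], dims[2])
  for (i in seq_len(dims[1])) {
    for (j in seq_len(dims[2])) {
      mean_read[i, j] <- mean(drm$readings[i, j, sample.int(nrep, nrep,
                                                            replace = TRUE)])
    }
  }
  inh <- 100 * (drm$neg_ctrl - mean_read) / (drm$neg_ctrl - drm$pos_ctrl)
  dimnames(inh) <- list(d1 = drm$doses1, d2 = drm$doses2)
  inh
}

# internal: combo-cell mask (both doses nonzero)
.combo_mask <- function(inh) row(inh) > 1 & col(inh) > 1

#' Fit a four-parameter logistic curve to monotherapy data
#'
#' Levenberg-Marquardt least squares of [four_pl()] with quartile-based
#' initialization, positive-slope parameterization and box constraints; falls
#' back to bounded Nelder-Mead/L-BFGS if the LM fit fails to converge.
#'
#' @param dose dose vector (zero allowed).
#' @param response inhibition responses (percent scale).
#' @param ymin_fixed optional fixed lower asymptote (used by the ZIP
#'   potency-shift fits).
#' @return named vector `c(ymin, ymax, ec50, slope)` with attribute
#'   `converged`.
#' @export
fit_4pl <- function(dose, response, ymin_fixed = NULL) {
  stopifnot(length(dose) == length(response))
  pos <- dose > 0
  if (sum(pos) < 3L) .halt("need at least three nonzero doses for a 4PL fit")
  rng <- range(dose[pos])
  y0 <- if (is.null(ymin_fixed)) min(response) else ymin_fixed
  y1 <- max(max(response), y0 + 1e-3)
  half <- (y0 + y1) / 2
  ec50_start <- dose[pos][which.min(abs(response[pos] - half))]
  start <- list(ymin = y0, ymax = y1, ec50 = max(ec50_start, rng[1] / 2),
                slope = 1)
  lower <- c(ymin = -50, ymax = y0, ec50 = rng[1] / 1000, slope = 0.05)
  upper <- c(ymin = y1, ymax = 200, ec50 = rng[2] * 1000, slope = 20)
  if (!is.null(ymin_fixed)) {
    start$ymin <- NULL
    lower <- lower[-1]
    upper <- upper[-1]
  }

  fit <- tryCatch({
    if (is.null(ymin_fixed)) {
      minpack.lm::nlsLM(response ~ four_pl(dose, ymin, ymax, ec50, slope),
                        start = start, lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(
        response ~ four_pl(dose, ymin_fixed, ymax, ec50, slope),
        start = start, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) NULL)

  if (!is.null(fit)) {
    cf <- coef(fit)
    out <- if (is.null(ymin_fixed)) {
      c(ymin = cf[["ymin"]], ymax = cf[["ymax"]], ec50 = cf[["ec50"]],
        slope = cf[["slope"]])
    } else {
      c(ymin = ymin_fixed, ymax = cf[["ymax"]], ec50 = cf[["ec50"]],
        slope = cf[["slope"]])
    }
    attr(out, "converged") <- TRUE
    return(out)
  }

  # fallback: bounded quasi-Newton on the residual sum of squares
  par0 <- unlist(start)
  obj <- function(p) {
    full <- if (is.null(ymin_fixed)) p else c(ymin = ymin_fixed, p)
    sum((response - four_pl(dose, full[["ymin"]], full[["ymax"]],
                            full[["ec50"]], full[["slope"]]))^2)
  }
  op <- optim(par0, obj, method = "L-BFGS-B", lower = lower, upper = upper)
  full <- if (is.null(ymin_fixed)) op$par else c(ymin = ymin_fixed, op$par)
  out <- c(ymin = full[["ymin"]], ymax = full[["ymax"]],
           ec50 = full[["ec50"]], slope = full[["slope"]])
  attr(out, "converged") <- op$convergence == 0
  out
}

#' Highest-single-agent (HSA) synergy excess
#'
#' Per combination cell, observed inhibition minus the better of the two
#' monotherapies at the component doses.
#'
#' @param inh inhibition surface from [to_inhibition()] (monotherapies in the
#'   first row/column).
#' @return list with `excess` (matrix, `NA` on monotherapy cells) and `mean`
#'   over combination cells.
#' @export
hsa_excess <- function(inh) {
  expected <- outer(inh[, 1], inh[1, ], pmax)
  .excess_result(inh, expected)
}

#' Bliss-independence synergy excess
#'
#' Expected combination inhibition `y1 + y2 - y1*y2` on the fraction scale,
#' reported in percentage points.
#'
#' @inheritParams hsa_excess
#' @return list with `excess` and `mean` as in [hsa_excess()].
#' @export
bliss_excess <- function(inh) {
  f1 <- inh[, 1] / 100
  f2 <- inh[1, ] / 100
  expected <- 100 * outer(f1, f2, function(a, b) a + b - a * b)
  .excess_result(inh, expected)
}

# internal: package observed-minus-expected over combination cells
.excess_result <- function(inh, expected, observed = NULL) {
  obs <- observed %||% inh
  excess <- obs - expected
  mask <- .combo_mask(inh)
  excess[!mask] <- NA_real_
  list(excess = excess, mean = mean(excess[mask], na.rm = TRUE))
}

#' Loewe-additivity synergy excess
#'
#' Fits four-parameter logistic curves to both monotherapies; the expected
#' combination response solves the Loewe equation
#' `d1/D1(y) + d2/D2(y) = 1` by bisection on the response scale (tolerance
#' 1e-6). Dose pairs whose equation has no root inside the shared response
#' range saturate at the nearer monotherapy asymptote and are flagged.
#'
#' @inheritParams hsa_excess
#' @return list with `excess`, `mean`, and the fitted monotherapy parameters
#'   (`fit1`, `fit2`).
#' @export
loewe_excess <- function(inh) {
  d1 <- as.numeric(rownames(inh))
  d2 <- as.numeric(colnames(inh))
  p1 <- fit_4pl(d1, inh[, 1])
  p2 <- fit_4pl(d2, inh[1, ])
  expected <- matrix(NA_real_, nrow(inh), ncol(inh))
  for (i in seq_along(d1)) {
    for (j in seq_along(d2)) {
      expected[i, j] <- .loewe_response(d1[i], d2[j], p1, p2)
    }
  }
  out <- .excess_result(inh, expected)
  out$fit1 <- p1
  out$fit2 <- p2
  out
}

#' Zero-interaction-potency (ZIP) synergy delta
#'
#' Fits monotherapy 4PL curves, then for each nonzero dose of one drug
#' refits the combination response along the other drug's axis with the lower
#' asymptote pinned to the fitted monotherapy effect (the potency-shift
#' fits). The delta per combination cell is the average of the two fitted
#' two-way responses minus the ZIP expectation
#' `y1 + y2 - y1*y2` from the fitted monotherapy curves (fraction scale,
#' reported in percentage points). Rows/columns whose constrained fit fails
#' fall back to the observed values.
#'
#' @inheritParams hsa_excess
#' @return list with `excess` (delta matrix), `mean`, `fit1`, `fit2`.
#' @export
zip_excess <- function(inh) {
  d1 <- as.numeric(rownames(inh))
  d2 <- as.numeric(colnames(inh))
  p1 <- fit_4pl(d1, inh[, 1])
  p2 <- fit_4pl(d2, inh[1, ])
  y1 <- four_pl(d1, p1[1], p1[2], p1[3], p1[4])
  y2 <- four_pl(d2, p2[1], p2[2], p2[3], p2[4])

  fit_line <- function(dose, resp, ymin_fixed) {
    p <- tryCatch(fit_4pl(dose, resp, ymin_fixed = ymin_fixed),
                  error = function(e) NULL)
    if (is.null(p)) return(resp)           # fallback: observed values
    four_pl(dose, p[1], p[2], p[3], p[4])
  }
  # fitted response along drug 1 within each nonzero dose of drug 2
  fit_cols <- matrix(NA_real_, nrow(inh), ncol(inh))
  for (j in seq_along(d2)[-1]) {
    fit_cols[, j] <- fit_line(d1, inh[, j], ymin_fixed = y2[j])
  }
  # fitted response along drug 2 within each nonzero dose of drug 1
  fit_rows <- matrix(NA_real_, nrow(inh), ncol(inh))
  for (i in seq_along(d1)[-1]) {
    fit_rows[i, ] <- fit_line(d2, inh[i, ], ymin_fixed = y1[i])
  }
  fitted_avg <- (fit_cols + fit_rows) / 2
  expected <- 100 * outer(y1 / 100, y2 / 100, function(a, b) a + b - a * b)
  out <- .excess_result(inh, expected, observed = fitted_avg)
  out$fit1 <- p1
  out$fit2 <- p2
  out
}

#' Classify a mean synergy score
#'
#' Mean synergy scores of at least 5 percentage points are called
#' synergistic (inclusive bound).
#'
#' @param mean_score finite numeric mean synergy score.
#' @return `"synergistic"` or `"not"`.
#' @export
classify_synergy <- function(mean_score) {
  stopifnot(is.finite(mean_score))
  if (mean_score >= 5) "synergistic" else "not"
}

# internal: mean synergy score of one model on an inhibition surface
.model_mean <- function(inh, model) {
  switch(model,
         hsa = hsa_excess(inh)$mean,
         bliss = bliss_excess(inh)$mean,
         loewe = loewe_excess(inh)$mean,
         zip = zip_excess(inh)$mean,
         .halt("unknown model: ", model))
}

#' Bootstrap significance of a mean synergy score
#'
#' Resamples replicate readings per well with replacement, recomputes the
#' mean synergy score, and reports the two-sided bootstrap P-value: twice the
#' (+1-corrected) fraction of bootstrap means on the opposite side of zero
#' from the observed mean, capped at 1. The conventional 10 iterations give
#' very coarse P-value resolution; 1000 or more is recommended when runtime
#' allows.
#'
#' @param drm a [dose_response_matrix()] with at least 2 replicate layers.
#' @param model one of `"hsa"`, `"bliss"`, `"loewe"`, `"zip"`.
#' @param n_boot bootstrap iterations (default 10).
#' @param seed integer seed.
#' @return list with `p`, `observed` mean score and the bootstrap `means`.
#' @export
bootstrap_significance <- function(drm, model = "bliss", n_boot = 10L,
                                   seed = 1L) {
  stopifnot(inherits(drm, "dose_response_matrix"))
  if (dim(drm$readings)[3] < 2L) {
    .halt("bootstrap needs >= 2 replicates per well; ",
          "consider a parametric test for single-replicate data")
  }
  if (n_boot < 100L) {
    warning("n_boot = ", n_boot, " gives coarse P-value resolution")
  }
  set.seed(seed)
  observed <- .model_mean(to_inhibition(drm), model)
  means <- vapply(seq_len(n_boot), function(k) {
    .model_mean(.inhibition_resampled(drm), model)
  }, numeric(1))
  opposite <- if (observed >= 0) sum(means < 0) else sum(means > 0)
  p <- min(1, 2 * (opposite + 1) / (n_boot + 1))
  list(p = p, observed = observed, means = means)
}

#' Score a dose-response matrix under the four reference models
#'
#' Normalizes the plate to percent inhibition and computes, for each
#' requested reference model, the per-cell synergy excess, its mean over
#' combination cells, the bootstrap P-value (when replicates allow) and the
#' synergistic call (mean score of at least 5).
#'
#' @param drm a [dose_response_matrix()].
#' @param models subset of `c("hsa", "bliss", "loewe", "zip")`.
#' @param n_boot bootstrap iterations (default 10; skipped with a single
#'   replicate).
#' @param seed integer seed.
#' @return object of class `synergy_result`: named list per model with
#'   `excess`, `mean`, `p`, `call`; the inhibition surface is attached as
#'   attribute `inhibition`.
#' @export
synergy_score <- function(drm, models = c("hsa", "bliss", "loewe", "zip"),
                          n_boot = 10L, seed = 1L) {
  models <- match.arg(models, several.ok = TRUE)
  inh <- to_inhibition(drm)
  n_rep <- dim(drm$readings)[3]
  out <- lapply(models, function(m) {
    res <- switch(m,
                  hsa = hsa_excess(inh),
                  bliss = bliss_excess(inh),
                  loewe = loewe_excess(inh),
                  zip = zip_excess(inh))
    p <- if (n_rep >= 2L) {
      suppressWarnings(bootstrap_significance(drm, m, n_boot, seed)$p)
    } else {
      NA_real_
    }
    list(excess = res$excess, mean = res$mean, p = p,
         call = classify_synergy(res$mean))
  })
  names(out) <- models
  attr(out, "inhibition") <- inh
  class(out) <- "synergy_result"
  out
}

#' @export
print.synergy_result <- function(x, ...) {
  for (m in names(x)) {
    cat(sprintf("%-6s mean score %7.2f  P %s  -> %s\n", m, x[[m]]$mean,
                ifelse(is.na(x[[m]]$p), "NA", format(x[[m]]$p, digits = 3)),
                x[[m]]$call))
  }
  invisible(x)
}
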