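#' Configuration for a synthetic sister-cell lineage-tracing experiment
#'
#' Bundles the generative parameters of the synthetic experiment: uniquely
#' barcoded lineages duplicate exactly once, the two daughters are split at
#' random between the profiled (pre-treatment) half and the treated half,
#' treatment kills a target fraction of cells as a logistic function of a
#' latent per-lineage resistance score, and UMI counts are drawn from an
#' overdispersed (negative binomial) model with heritable (lineage-shared)
#' log-expression.
#'
#' @param n_lineages number of barcoded lineages per arm.
#' @param n_genes number of genes.
#' @param heritability fraction of a gene's biological log-expression variance
#'   attributable to the lineage-shared latent factor; scalar or per-gene
#'   vector of length `n_genes`.
#' @param n_resistance_genes number of genes coupled to the latent resistance
#'   score.
#' @param resistance_effect log2-scale expression shift of resistance genes per
#'   unit resistance score.
#' @param n_fitness_genes number of genes coupled to the latent growth-fitness
#'   score.
#' @param fitness_effect log2-scale shift of fitness genes per unit fitness
#'   score; defaults to `resistance_effect`.
#' @param kill_fraction target expected death rate among treated cells
#'   (default 0.70).
#' @param control_kill_fraction expected loss rate in the vehicle-control arm,
#'   driven by the fitness score; defaults to `kill_fraction` so both arms have
#'   comparable detection power.
#' @param survival_slope slope of the logistic survival link on the latent
#'   score; the intercept is solved numerically so the expected death rate
#'   equals the requested kill fraction.
#' @param fitness_weight_treatment weight of the fitness score inside the
#'   treatment arm's survival score (resistance + weight * fitness). A positive
#'   value makes the pre-resistance signature partially overlap the
#'   pre-fitness signature, as observed in real experiments.
#' @param mean_depth expected total UMI count per cell.
#' @param libsize_sd log-normal standard deviation of per-cell library size.
#' @param baseline_sd log-normal standard deviation of per-gene relative
#'   abundance.
#' @param bio_sd biological log-expression standard deviation per gene
#'   (natural-log scale), split between lineage and cell according to
#'   `heritability`.
#' @param dispersion negative-binomial overdispersion phi (variance =
#'   mu + phi * mu^2).
#' @param barcode_error_rate per-base substitution probability used by
#'   [corrupt_reads()].
#' @param seed integer seed; identical config + seed give byte-identical
#'   output.
#'
#' @return an object of class `sim_config` (a validated list).
#' @seealso [simulate_experiment()]
#' @export
sim_config <- function(n_lineages = 2000,
                       n_genes = 2000,
                       heritability = 0.6,
                       n_resistance_genes = 200,
                       resistance_effect = 0.5,
                       n_fitness_genes = 200,
                       fitness_effect = resistance_effect,
                       kill_fraction = 0.70,
                       control_kill_fraction = kill_fraction,
                       survival_slope = 2,
                       fitness_weight_treatment = 0.5,
                       mean_depth = 20000,
                       libsize_sd = 0.25,
                       baseline_sd = 1.5,
                       bio_sd = 0.35,
                       dispersion = 0.05,
                       barcode_error_rate = 0.01,
                       seed = 1L) {
  stopifnot(n_lineages >= 1, n_genes >= 1, mean_depth > 0, dispersion > 0,
            resistance_effect >= 0, fitness_effect >= 0,
            n_resistance_genes >= 0, n_fitness_genes >= 0)
  .check_fraction(heritability, "heritability")
  .check_fraction(kill_fraction, "kill_fraction")
  .check_fraction(control_kill_fraction, "control_kill_fraction")
  .check_fraction(barcode_error_rate, "barcode_error_rate")
  if (n_resistance_genes + n_fitness_genes > n_genes) {
    .halt("n_resistance_genes + n_fitness_genes must not exceed n_genes")
  }
  if (!length(heritability) %in% c(1L, n_genes)) {
    .halt("heritability must be a scalar or a vector of length n_genes")
  }
  if (kill_fraction %in% c(0, 1)) {
    warning("kill_fraction of ", kill_fraction,
            " gives a degenerate fate partition (all cells share one fate)")
  }
  cfg <- list(n_lineages = as.integer(n_lineages),
              n_genes = as.integer(n_genes),
              heritability = heritability,
              n_resistance_genes = as.integer(n_resistance_genes),
              resistance_effect = resistance_effect,
              n_fitness_genes = as.integer(n_fitness_genes),
              fitness_effect = fitness_effect,
              kill_fraction = kill_fraction,
              control_kill_fraction = control_kill_fraction,
              survival_slope = survival_slope,
              fitness_weight_treatment = fitness_weight_treatment,
              mean_depth = mean_depth,
              libsize_sd = libsize_sd,
              baseline_sd = baseline_sd,
              bio_sd = bio_sd,
              dispersion = dispersion,
              barcode_error_rate = barcode_error_rate,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a library of unique 20-base lineage labels
#'
#' Labels are 20-character strings over `{A,C,G,T}`, resampled on collision so
#' that all lineages receive distinct labels.
#'
#' @param n_lineages number of labels to draw.
#' @param seed integer seed.
#' @param label_length label length in bases (default 20).
#' @return named character vector, names `L1..Ln` (lineage ids).
#' @export
generate_barcode_library <- function(n_lineages, seed = 1L, label_length = 20L) {
  stopifnot(n_lineages >= 1)
  if (log(n_lineages) > label_length * log(4)) {
    .halt("n_lineages exceeds the number of distinct labels of this length")
  }
  set.seed(seed)
  draw <- function(n) {
    m <- matrix(sample(c("A", "C", "G", "T"), n * label_length, replace = TRUE),
                nrow = n)
    apply(m, 1L, paste0, collapse = "")
  }
  labels <- draw(n_lineages)
  while (anyDuplicated(labels)) {
    dup <- which(duplicated(labels))
    labels[dup] <- draw(length(dup))
  }
  names(labels) <- paste0("L", seq_len(n_lineages))
  labels
}

# internal: solve the logistic survival intercept so that the mean survival
# probability over the realized latent scores equals 1 - kill_fraction
.solve_survival_intercept <- function(scores, slope, kill_fraction) {
  if (kill_fraction <= 0) return(Inf)
  if (kill_fraction >= 1) return(-Inf)
  f <- function(a) mean(plogis(a + slope * scores)) - (1 - kill_fraction)
  uniroot(f, lower = -50, upper = 50, tol = 1e-10)$root
}

# internal: negative-binomial counts for a set of cells.
# log_expr: genes x cells matrix of centred log-scale expression offsets;
# gene_weight: baseline relative abundance; returns genes x cells dgCMatrix.
.draw_counts <- function(log_expr, gene_weight, depth, dispersion) {
  theta <- gene_weight * exp(log_expr)
  theta <- sweep(theta, 2L, colSums(theta), "/")
  mu <- sweep(theta, 2L, depth, "*")
  counts <- matrix(rnbinom(length(mu), mu = as.vector(mu),
                           size = 1 / dispersion),
                   nrow = nrow(mu), dimnames = dimnames(mu))
  methods::as(Matrix(counts, sparse = TRUE), "CsparseMatrix")
}

# internal: assemble a SingleCellExperiment from counts + cell metadata
.make_sce <- function(counts, meta) {
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(meta, row.names = meta$cell_id))
}

# internal: simulate one arm (treatment or control)
.simulate_arm <- function(cfg, arm, genes, gene_weight, h, labels, sample_prefix) {
  nl <- cfg$n_lineages
  ng <- cfg$n_genes
  lineages <- names(labels)

  r_score <- rnorm(nl)            # latent resistance score, N(0,1)
  f_score <- rnorm(nl)            # latent growth-fitness score, N(0,1)

  # per-lineage, per-gene shared factor; per-cell noise added later
  lin_factor <- matrix(rnorm(ng * nl), nrow = ng)

  # fixed log2-scale effects on the flagged gene sets
  res_idx <- attr(genes, "resistance_idx")
  fit_idx <- attr(genes, "fitness_idx")
  effect <- matrix(0, nrow = ng, ncol = nl)
  if (length(res_idx)) {
    effect[res_idx, ] <- effect[res_idx, ] +
      log(2) * cfg$resistance_effect * rep(r_score, each = length(res_idx))
  }
  if (length(fit_idx)) {
    effect[fit_idx, ] <- effect[fit_idx, ] +
      log(2) * cfg$fitness_effect * rep(f_score, each = length(fit_idx))
  }

  # each lineage contributes exactly two daughters; each daughter enters the
  # profiled (pre) half with probability 0.5, else the treated half
  daughter_lineage <- rep(seq_len(nl), each = 2L)
  in_pre <- rbinom(2L * nl, 1L, 0.5) == 1L

  # survival of treated daughters: logistic in the arm's latent score
  surv_score <- if (arm == "treatment") {
    r_score + cfg$fitness_weight_treatment * f_score
  } else {
    f_score
  }
  kill <- if (arm == "treatment") cfg$kill_fraction else cfg$control_kill_fraction
  treated_idx <- which(!in_pre)
  treated_scores <- surv_score[daughter_lineage[treated_idx]]
  intercept <- .solve_survival_intercept(treated_scores, cfg$survival_slope, kill)
  p_surv <- plogis(intercept + cfg$survival_slope * treated_scores)
  survived <- rbinom(length(treated_idx), 1L, p_surv) == 1L

  pre_idx <- which(in_pre)
  post_idx <- treated_idx[survived]

  draw_sample <- function(idx, tag) {
    if (!length(idx)) {
      counts <- Matrix(0L, nrow = ng, ncol = 0L, sparse = TRUE,
                       dimnames = list(genes, character(0)))
      meta <- data.frame(cell_id = character(0), sample = character(0),
                         lineage = character(0), label = character(0),
                         stringsAsFactors = FALSE)
      return(.make_sce(counts, meta))
    }
    lin <- daughter_lineage[idx]
    n <- length(idx)
    sqh <- sqrt(h)
    sq1h <- sqrt(1 - h)
    log_expr <- cfg$bio_sd *
      (sqh * lin_factor[, lin, drop = FALSE] +
       sq1h * matrix(rnorm(ng * n), nrow = ng)) +
      effect[, lin, drop = FALSE]
    depth <- cfg$mean_depth *
      exp(rnorm(n, sd = cfg$libsize_sd) - cfg$libsize_sd^2 / 2)
    counts <- .draw_counts(log_expr, gene_weight, depth, cfg$dispersion)
    cell_id <- sprintf("%s_%s_c%04d", sample_prefix, tag, seq_len(n))
    dimnames(counts) <- list(genes, cell_id)
    meta <- data.frame(cell_id = cell_id,
                       sample = paste0(sample_prefix, "_", tag),
                       lineage = lineages[lin],
                       label = unname(labels[lin]),
                       stringsAsFactors = FALSE)
    .make_sce(counts, meta)
  }

  pre <- draw_sample(pre_idx, "pre")
  post <- draw_sample(post_idx, "post")

  lineage_tab <- data.frame(
    lineage = lineages,
    label = unname(labels),
    arm = arm,
    resistance_score = r_score,
    fitness_score = f_score,
    n_pre_cells = tabulate(daughter_lineage[pre_idx], nbins = nl),
    n_treated_cells = tabulate(daughter_lineage[treated_idx], nbins = nl),
    survived = seq_len(nl) %in% daughter_lineage[post_idx],
    stringsAsFactors = FALSE)

  list(pre = pre, post = post, lineages = lineage_tab,
       realized_kill = 1 - mean(survived))
}

#' Simulate a full sister-cell lineage-tracing experiment
#'
#' Generates a treatment arm and a vehicle-control arm, each with a
#' pre-treatment (profiled) sample and a post-treatment (survivor) sample,
#' plus the ground truth needed to validate every downstream stage. Each
#' lineage contributes exactly two daughter cells (one duplication); each
#' daughter independently enters the pre half or the treated half, so
#' singleton and doubleton pre-lineages arise naturally. Survival of treated
#' cells is Bernoulli with logistic probability in the arm's latent score,
#' with the intercept calibrated so the expected death rate equals the
#' configured kill fraction.
#'
#' @param config a [sim_config()] object.
#' @return a list with elements `pre`, `post`, `control_pre`, `control_post`
#'   ([SingleCellExperiment::SingleCellExperiment] objects, genes x cells,
#'   assay `"counts"`, colData columns `cell_id`, `sample`, `lineage`,
#'   `label`) and `truth` (a list with `resistance_genes`, `fitness_genes`,
#'   `labels`, per-lineage tables `lineages_treatment` / `lineages_control`,
#'   realized kill fractions and the config).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)

  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  special <- sample(cfg$n_genes, cfg$n_resistance_genes + cfg$n_fitness_genes)
  res_idx <- head(special, cfg$n_resistance_genes)
  fit_idx <- tail(special, cfg$n_fitness_genes)
  attr(genes, "resistance_idx") <- res_idx
  attr(genes, "fitness_idx") <- fit_idx

  gene_weight <- exp(rnorm(cfg$n_genes, sd = cfg$baseline_sd))
  gene_weight <- gene_weight / sum(gene_weight)
  h <- rep_len(cfg$heritability, cfg$n_genes)

  labels <- generate_barcode_library(2L * cfg$n_lineages,
                                     seed = sample.int(.Machine$integer.max, 1))
  treat_labels <- labels[seq_len(cfg$n_lineages)]
  ctrl_labels <- labels[cfg$n_lineages + seq_len(cfg$n_lineages)]
  names(ctrl_labels) <- paste0("LC", seq_len(cfg$n_lineages))

  treat <- .simulate_arm(cfg, "treatment", genes, gene_weight, h,
                         treat_labels, "treat")
  ctrl <- .simulate_arm(cfg, "control", genes, gene_weight, h,
                        ctrl_labels, "ctrl")

  truth <- list(
    resistance_genes = genes[res_idx],
    fitness_genes = genes[fit_idx],
    labels = c(treat_labels, ctrl_labels),
    lineages_treatment = treat$lineages,
    lineages_control = ctrl$lineages,
    realized_kill_treatment = treat$realized_kill,
    realized_kill_control = ctrl$realized_kill,
    config = cfg)

  list(pre = treat$pre, post = treat$post,
       control_pre = ctrl$pre, control_post = ctrl$post,
       truth = truth)
}

# the fixed barcode construct: five 4-base informative blocks separated by
# anchor dinucleotides, with full-construct flanks
.BARCODE_SUBPATTERN <- "CANNNNTGNNNNACNNNNGANNNNGTNNNNCT"
.BARCODE_FLANK5 <- "CTGGGGCACAAGCTTAATTAAGAATT"
.BARCODE_FLANK3 <- "AGGGCCTAGAGGGCCCGTTTAAAC"

#' Simulate barcode-bearing reads with substitution errors
#'
#' Each read is the full barcode construct (5' flank, anchor sub-pattern with
#' the cell's 20 informative bases, 3' flank); each informative base is
#' substituted independently with probability `error_rate`. Anchor and flank
#' bases can optionally be corrupted at the same rate.
#'
#' @param cell_labels named character vector: true 20-base label per cell id.
#' @param reads_per_cell number of reads per cell.
#' @param error_rate per-base substitution probability, in `[0, 0.25]`.
#' @param seed integer seed.
#' @param corrupt_anchors also corrupt anchor/flank bases (default FALSE).
#' @return data.frame with columns `cell_id`, `read`.
#' @export
corrupt_reads <- function(cell_labels, reads_per_cell = 10L,
                          error_rate = 0.01, seed = 1L,
                          corrupt_anchors = FALSE) {
  stopifnot(length(cell_labels) >= 1, reads_per_cell >= 1)
  if (error_rate < 0 || error_rate > 0.25) {
    .halt("error_rate must lie in [0, 0.25]")
  }
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  n_reads <- length(cell_labels) * reads_per_cell
  lab <- rep(unname(cell_labels), each = reads_per_cell)
  chars <- matrix(unlist(strsplit(lab, ""), use.names = FALSE),
                  nrow = n_reads, byrow = TRUE)
  flip <- matrix(runif(length(chars)) < error_rate, nrow = n_reads)
  if (any(flip)) {
    # substitute with one of the three other bases, uniformly
    cur <- chars[flip]
    sub <- vapply(cur, function(b) sample(setdiff(bases, b), 1L), "")
    chars[flip] <- sub
  }
  labels_err <- apply(chars, 1L, paste0, collapse = "")

  # weave the (possibly corrupted) informative bases into the construct
  tpl <- strsplit(.BARCODE_SUBPATTERN, "")[[1]]
  n_pos <- which(tpl == "N")
  body <- vapply(labels_err, function(x) {
    tpl[n_pos] <- strsplit(x, "")[[1]]
    paste0(tpl, collapse = "")
  }, "", USE.NAMES = FALSE)
  reads <- paste0(.BARCODE_FLANK5, body, .BARCODE_FLANK3)

  if (corrupt_anchors) {
    rc <- strsplit(reads, "")
    reads <- vapply(rc, function(ch) {
      hit <- runif(length(ch)) < error_rate
      if (any(hit)) {
        ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(bases, b), 1L), "")
      }
      paste0(ch, collapse = "")
    }, "")
  }
  data.frame(cell_id = rep(names(cell_labels), each = reads_per_cell),
             read = reads, stringsAsFactors = FALSE)
}

#' Four-parameter logistic response
#'
#' Inhibition as a function of dose: `ymin + (ymax - ymin) / (1 +
#' (ec50/d)^slope)`, with `y(0) = ymin`.
#'
#' @param d dose (same units as `ec50`); may be zero.
#' @param ymin,ymax lower/upper asymptotes (inhibition %).
#' @param ec50 dose of half-maximal effect.
#' @param slope Hill slope (positive for increasing inhibition).
#' @return numeric vector of responses.
#' @export
four_pl <- function(d, ymin, ymax, ec50, slope) {
  y <- rep(ymin, length(d))
  pos <- d > 0
  y[pos] <- ymin + (ymax - ymin) / (1 + (ec50 / d[pos])^slope)
  y
}

#' Simulate a dose-response combination matrix with a known null model
#'
#' Monotherapy rows/columns follow four-parameter logistic curves; combination
#' wells follow the named reference null model plus a planted synergy shift
#' plus Gaussian noise. Readings are emitted on a viability scale anchored to
#' plate controls (negative/growth control 100, positive/total-kill control 0),
#' so the inhibition surface recovered by [to_inhibition()] equals the
#' generated truth.
#'
#' @param model `"bliss-null"`, `"hsa-null"` or `"additive-shift"` (Loewe
#'   dose-additive null).
#' @param doses1,doses2 dose grids (zero dose added if absent).
#' @param mono1,mono2 4PL parameter vectors `c(ymin, ymax, ec50, slope)` on the
#'   inhibition-% scale.
#' @param synergy_delta planted shift of every combination well, in inhibition
#'   percentage points.
#' @param noise_sd Gaussian noise sd (percentage points) added per replicate
#'   well.
#' @param replicates number of replicate layers sharing the truth.
#' @param seed integer seed.
#' @return a [dose_response_matrix()] object.
#' @export
simulate_dose_response <- function(model = c("bliss-null", "hsa-null",
                                             "additive-shift"),
                                   doses1, doses2,
                                   mono1 = c(ymin = 0, ymax = 90, ec50 = 1,
                                             slope = 1.5),
                                   mono2 = c(ymin = 0, ymax = 80, ec50 = 5,
                                             slope = 1.2),
                                   synergy_delta = 0, noise_sd = 0,
                                   replicates = 3L, seed = 1L) {
  model <- match.arg(model)
  if (noise_sd < 0) .halt("noise_sd must be non-negative")
  doses1 <- sort(unique(c(0, doses1)))
  doses2 <- sort(unique(c(0, doses2)))
  if (length(doses1) < 3L || length(doses2) < 3L) {
    .halt("need at least two nonzero doses per drug plus the zero dose")
  }
  set.seed(seed)
  y1 <- four_pl(doses1, mono1[1], mono1[2], mono1[3], mono1[4])
  y2 <- four_pl(doses2, mono2[1], mono2[2], mono2[3], mono2[4])
  truth <- switch(model,
    "bliss-null" = outer(y1 / 100, y2 / 100,
                         function(a, b) 100 * (a + b - a * b)),
    "hsa-null" = outer(y1, y2, pmax),
    "additive-shift" = {
      m <- matrix(NA_real_, length(doses1), length(doses2))
      for (i in seq_along(doses1)) {
        for (j in seq_along(doses2)) {
          m[i, j] <- .loewe_response(doses1[i], doses2[j], mono1, mono2)
        }
      }
      m
    })
  # monotherapy rows/columns carry the pure curves
  truth[, 1] <- y1
  truth[1, ] <- y2
  combo <- row(truth) > 1 & col(truth) > 1
  truth[combo] <- truth[combo] + synergy_delta

  readings <- array(NA_real_,
                    dim = c(length(doses1), length(doses2), replicates),
                    dimnames = list(d1 = doses1, d2 = doses2,
                                    rep = seq_len(replicates)))
  for (r in seq_len(replicates)) {
    noise <- matrix(rnorm(length(truth), sd = noise_sd), nrow = nrow(truth))
    readings[, , r] <- 100 - (truth + noise)   # viability on the control scale
  }
  dose_response_matrix(doses1, doses2, readings,
                       neg_ctrl = 100, pos_ctrl = 0,
                       truth = truth, model = model)
}

# internal: Loewe dose-additive expected response for two 4PL curves
# (used both to generate additive-shift surfaces and to score Loewe excess)
.loewe_response <- function(d1, d2, p1, p2, tol = 1e-6) {
  if (d1 == 0 && d2 == 0) return(four_pl(0, p1[1], p1[2], p1[3], p1[4]))
  if (d2 == 0) return(four_pl(d1, p1[1], p1[2], p1[3], p1[4]))
  if (d1 == 0) return(four_pl(d2, p2[1], p2[2], p2[3], p2[4]))
  inv <- function(y, p) {
    # dose achieving response y under a 4PL curve
    frac <- (y - p[1]) / (p[2] - y)
    p[3] * frac^(1 / p[4])
  }
  lo <- max(p1[1], p2[1]) + tol
  hi <- min(p1[2], p2[2]) - tol
  if (lo >= hi) return(min(p1[2], p2[2]))
  g <- function(y) d1 / inv(y, p1) + d2 / inv(y, p2) - 1
  glo <- g(lo); ghi <- g(hi)
  if (is.na(glo) || is.na(ghi) || glo * ghi > 0) {
    # no root inside the shared response range: saturate at the nearer bound
    return(if (!is.na(ghi) && ghi > 0) hi else lo)
  }
  uniroot(g, lower = lo, upper = hi, tol = tol)$root
}
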