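# internal: vectorized two-sided Wilcoxon rank-sum test (tie-corrected normal
# approximation with continuity correction), one test per matrix row.
# Group A = columns in `ia`, group B = columns in `ib`.
.row_wilcox <- function(mat, ia, ib) {
  na <- length(ia)
  nb <- length(ib)
  n <- na + nb
  sub <- mat[, c(ia, ib), drop = FALSE]
  p <- numeric(nrow(sub))
  w <- numeric(nrow(sub))
  for (g in seq_len(nrow(sub))) {
    x <- sub[g, ]
    r <- rank(x)
    W <- sum(r[seq_len(na)]) - na * (na + 1) / 2
    ties <- table(x)
    tie_term <- sum(ties^3 - ties)
    sigma2 <- (na * nb / 12) * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) {
      p[g] <- 1
      w[g] <- W
      next
    }
    mu <- na * nb / 2
    z <- W - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)   # continuity correction
    p[g] <- min(1, 2 * pnorm(-abs(z)))
    w[g] <- W
  }
  list(statistic = w, p = p)
}

# internal: log2 fold change of group means on the unlogged expression scale
.group_l2fc <- function(mean_a, mean_b, pseudocount) {
  log2((mean_a + pseudocount) / (mean_b + pseudocount))
}

#' Differential expression by Wilcoxon rank-sum test
#'
#' Per gene, a two-sided Wilcoxon rank-sum test on normalized values between
#' two cell groups (tie-corrected normal approximation), with
#' `log2FC = log2((mean_A + p) / (mean_B + p))` computed on the
#' normalized-then-unlogged expression with pseudocount `p`. No fold-change or
#' expression-fraction thresholds are applied; P-values are BH-adjusted over
#' all tested genes. Positive log2FC means higher expression in group A
#' (e.g. pre-resistant). Callers deriving pre-resistance signatures should
#' pass singleton-lineage cells only (see [singleton_cells()]).
#'
#' @param mat numeric matrix, genes x cells, log-normalized values.
#' @param cells_a,cells_b disjoint character vectors of cell ids (each of
#'   size >= 3).
#' @param pseudocount pseudocount for the fold-change ratio (default 1).
#' @return object of class `gene_signature`: data.frame with `gene`,
#'   `log2fc`, `p`, `padj`, `pct_a`, `pct_b`.
#' @export
differential_expression <- function(mat, cells_a, cells_b, pseudocount = 1) {
  if (length(cells_a) < 3L || length(cells_b) < 3L) {
    .halt("each group must contain at least three cells")
  }
  if (length(intersect(cells_a, cells_b))) .halt("groups must be disjoint")
  cells <- colnames(mat)
  miss <- setdiff(c(cells_a, cells_b), cells)
  if (length(miss)) .halt("unknown cell id(s): ", paste(head(miss, 3), collapse = ", "))
  ia <- match(cells_a, cells)
  ib <- match(cells_b, cells)
  wt <- .row_wilcox(mat, ia, ib)
  E <- expm1(mat)
  mean_a <- rowMeans(E[, ia, drop = FALSE])
  mean_b <- rowMeans(E[, ib, drop = FALSE])
  out <- data.frame(
    gene = rownames(mat),
    log2fc = .group_l2fc(mean_a, mean_b, pseudocount),
    p = wt$p,
    padj = p.adjust(wt$p, method = "BH"),
    pct_a = rowMeans(mat[, ia, drop = FALSE] > 0),
    pct_b = rowMeans(mat[, ib, drop = FALSE] > 0),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("gene_signature", "data.frame")
  out
}

# internal: sparse resampling-weight matrix; each column holds one bootstrap
# draw (counts of resampled cells) over `n` cells
.boot_weights <- function(n, n_iter) {
  idx <- sample.int(n, n * n_iter, replace = TRUE)
  Matrix::sparseMatrix(i = idx, j = rep(seq_len(n_iter), each = n), x = 1,
                       dims = c(n, n_iter))
}

# internal: sparse indicator matrix of permuted group-A membership;
# column = one permutation, rows = cells of the arm
.perm_weights <- function(n, n_a, n_iter) {
  idx <- unlist(lapply(seq_len(n_iter), function(k) sample.int(n, n_a)),
                use.names = FALSE)
  Matrix::sparseMatrix(i = idx, j = rep(seq_len(n_iter), each = n_a), x = 1,
                       dims = c(n, n_iter))
}

#' Resistance-specificity of signature genes by bootstrap and permutation
#'
#' Contrasts the pre-resistance log2FC (treatment arm: pre-resistant vs
#' pre-sensitive) against the pre-fitness log2FC (control arm: pre-fit vs
#' pre-unfit). For each gene, `delta = log2FC_resistance - log2FC_fitness`.
#' The bootstrap resamples cells with replacement within each of the four
#' groups and reports the one-sided P-value for up-regulated genes (fraction
#' of bootstrap deltas at or below zero). The permutation test shuffles fate
#' labels within each arm and reports the two-sided P-value (fraction of
#' permuted `|delta|` at or above the observed). Both use the +1 correction.
#'
#' @param mat_treat,mat_ctrl numeric matrices (genes x cells) of
#'   log-normalized values for the treatment and control arms; gene universes
#'   are intersected.
#' @param res_cells,sens_cells cell ids of the pre-resistant / pre-sensitive
#'   groups (columns of `mat_treat`).
#' @param fit_cells,unfit_cells cell ids of the pre-fit / pre-unfit groups
#'   (columns of `mat_ctrl`).
#' @param n_boot,n_perm resampling iterations (default 1000; a warning is
#'   issued below 100).
#' @param seed integer seed.
#' @param pseudocount pseudocount for fold changes (default 1).
#' @param signature optional `gene_signature` for the treatment arm (from
#'   [differential_expression()]); when given, a `specific` flag is added:
#'   signature `padj < alpha` AND both resampling P `< alpha` AND
#'   `delta > 0`.
#' @param alpha significance level for the `specific` flag (default 0.05).
#' @return data.frame per gene: `delta_log2fc`, `log2fc_resistance`,
#'   `log2fc_fitness`, `p_boot`, `p_perm` (and `specific` when `signature`
#'   is supplied).
#' @export
specificity_test <- function(mat_treat, res_cells, sens_cells,
                             mat_ctrl, fit_cells, unfit_cells,
                             n_boot = 1000L, n_perm = 1000L, seed = 1L,
                             pseudocount = 1, signature = NULL,
                             alpha = 0.05) {
  if (n_boot < 100L || n_perm < 100L) {
    warning("fewer than 100 resampling iterations give coarse P-values")
  }
  genes <- intersect(rownames(mat_treat), rownames(mat_ctrl))
  if (!length(genes)) .halt("no shared genes between the two arms")
  set.seed(seed)

  Et <- expm1(mat_treat[genes, c(res_cells, sens_cells), drop = FALSE])
  Ec <- expm1(mat_ctrl[genes, c(fit_cells, unfit_cells), drop = FALSE])
  na <- length(res_cells); nb <- length(sens_cells)
  nc <- length(fit_cells); nd <- length(unfit_cells)
  ia <- seq_len(na); ib <- na + seq_len(nb)
  ic <- seq_len(nc); id <- nc + seq_len(nd)

  l2fc <- function(ma, mb) .group_l2fc(ma, mb, pseudocount)
  obs_res <- l2fc(rowMeans(Et[, ia, drop = FALSE]),
                  rowMeans(Et[, ib, drop = FALSE]))
  obs_fit <- l2fc(rowMeans(Ec[, ic, drop = FALSE]),
                  rowMeans(Ec[, id, drop = FALSE]))
  delta <- obs_res - obs_fit

  # bootstrap: resample cells with replacement within each of the 4 groups
  mA <- as.matrix(Et[, ia, drop = FALSE] %*% .boot_weights(na, n_boot)) / na
  mB <- as.matrix(Et[, ib, drop = FALSE] %*% .boot_weights(nb, n_boot)) / nb
  mC <- as.matrix(Ec[, ic, drop = FALSE] %*% .boot_weights(nc, n_boot)) / nc
  mD <- as.matrix(Ec[, id, drop = FALSE] %*% .boot_weights(nd, n_boot)) / nd
  delta_boot <- l2fc(mA, mB) - l2fc(mC, mD)
  p_boot <- (1 + rowSums(delta_boot <= 0)) / (n_boot + 1)

  # permutation: shuffle fate labels within each arm
  nt <- na + nb; nu <- nc + nd
  Pt <- .perm_weights(nt, na, n_perm)
  Pc <- .perm_weights(nu, nc, n_perm)
  sum_t <- rowSums(Et); sum_c <- rowSums(Ec)
  mA_p <- as.matrix(Et %*% Pt) / na
  mB_p <- (sum_t - mA_p * na) / nb
  mC_p <- as.matrix(Ec %*% Pc) / nc
  mD_p <- (sum_c - mC_p * nc) / nd
  delta_perm <- l2fc(mA_p, mB_p) - l2fc(mC_p, mD_p)
  p_perm <- (1 + rowSums(abs(delta_perm) >= abs(delta))) / (n_perm + 1)

  out <- data.frame(gene = genes,
                    delta_log2fc = delta,
                    log2fc_resistance = obs_res,
                    log2fc_fitness = obs_fit,
                    p_boot = p_boot,
                    p_perm = p_perm,
                    stringsAsFactors = FALSE)
  if (!is.null(signature)) {
    padj <- signature$padj[match(genes, signature$gene)]
    out$specific <- !is.na(padj) & padj < alpha &
      p_boot < alpha & p_perm < alpha & delta > 0
  }
  rownames(out) <- NULL
  out
}

#' Assemble the four pre-resistance signature variants
#'
#' The four query variants used for drug-signature matching, all restricted
#' to sister-concordant genes:
#' 1. the full pre-resistance log2FC;
#' 2. the pre-resistance log2FC restricted to genes with Wilcoxon
#'    `P < wilcox_alpha`;
#' 3. the contrast log2FC (pre-resistance minus pre-fitness);
#' 4. the contrast log2FC restricted to genes with bootstrap
#'    `P < boot_alpha`.
#'
#' @param res_sig `gene_signature` of the treatment arm.
#' @param fit_sig `gene_signature` of the control arm.
#' @param spec result of [specificity_test()].
#' @param concordant_genes character vector of sister-concordant genes.
#' @param wilcox_alpha raw Wilcoxon P cutoff for variant 2 (default 0.05).
#' @param boot_alpha bootstrap P cutoff for variant 4 (default 0.05).
#' @return object of class `signature_variants`: named list of four numeric
#'   gene-weight vectors.
#' @export
build_signature_variants <- function(res_sig, fit_sig, spec, concordant_genes,
                                     wilcox_alpha = 0.05, boot_alpha = 0.05) {
  shared <- Reduce(intersect, list(res_sig$gene, fit_sig$gene, spec$gene))
  v1_genes <- intersect(res_sig$gene, concordant_genes)
  v1 <- setNames(res_sig$log2fc[match(v1_genes, res_sig$gene)], v1_genes)
  v2_genes <- v1_genes[res_sig$p[match(v1_genes, res_sig$gene)] < wilcox_alpha]
  v2 <- v1[v2_genes]
  v3_genes <- intersect(shared, concordant_genes)
  v3 <- setNames(spec$delta_log2fc[match(v3_genes, spec$gene)], v3_genes)
  v4_genes <- v3_genes[spec$p_boot[match(v3_genes, spec$gene)] < boot_alpha]
  v4 <- v3[v4_genes]
  variants <- list(full = v1, wilcox_filtered = v2,
                   contrast = v3, contrast_boot_filtered = v4)
  empty <- names(variants)[lengths(variants) == 0L]
  if (length(empty)) {
    .halt("empty signature variant(s) after filtering: ",
          paste(empty, collapse = ", "))
  }
  structure(variants, class = "signature_variants")
}
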