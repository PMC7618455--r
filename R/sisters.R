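#' Extract a log-normalized expression matrix
#'
#' Convenience accessor: the `lognorm` assay (computed by [normalize_log()]),
#' optionally restricted to a gene set, as a dense base matrix (genes x
#' cells).
#'
#' @param sce a [SingleCellExperiment::SingleCellExperiment].
#' @param genes optional character vector of genes to keep, in order.
#' @return dense numeric matrix.
#' @export
lognorm_matrix <- function(sce, genes = NULL) {
  m <- SummarizedExperiment::assay(sce, "lognorm")
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  as.matrix(m)
}

# internal: Euclidean distances between paired columns of a matrix, chunked
.pair_dist <- function(mat, a, b, chunk = 5000L) {
  n <- length(a)
  out <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    d <- mat[, a[s:e], drop = FALSE] - mat[, b[s:e], drop = FALSE]
    out[s:e] <- sqrt(colSums(d * d))
  }
  out
}

#' Distances of sister pairs and random cell pairs
#'
#' Computes the Euclidean distance of every sister pair and of `n_random`
#' uniformly sampled non-sister cell pairs over the supplied expression
#' matrix (typically log-normalized values restricted to the top variable
#' genes). If `n_random` is at least the number of available non-sister
#' pairs, all of them are used.
#'
#' @param mat numeric matrix, genes x cells (see [lognorm_matrix()]).
#' @param pairs data.frame from [sister_pairs()] (`cell_a`, `cell_b`).
#' @param n_random number of random non-sister pairs (default 100000).
#' @param seed integer seed for the random-pair sample.
#' @return data.frame with columns `cell_a`, `cell_b`, `type`
#'   (`"sister"`/`"random"`), `distance`.
#' @export
pair_distances <- function(mat, pairs, n_random = 100000L, seed = 1L) {
  cells <- colnames(mat)
  miss <- setdiff(c(pairs$cell_a, pairs$cell_b), cells)
  if (length(miss)) {
    .halt("pair(s) reference cells absent from the matrix: ",
          paste(head(miss, 3L), collapse = ", "))
  }
  set.seed(seed)
  n <- ncol(mat)
  ia <- match(pairs$cell_a, cells)
  ib <- match(pairs$cell_b, cells)
  sis_key <- paste(pmin(ia, ib), pmax(ia, ib))

  total_pairs <- n * (n - 1) / 2
  n_avail <- total_pairs - length(unique(sis_key))
  if (n_random >= n_avail) {
    cmb <- combn(n, 2L)
    key <- paste(cmb[1L, ], cmb[2L, ])
    keep <- !(key %in% sis_key)
    ra <- cmb[1L, keep]
    rb <- cmb[2L, keep]
  } else {
    ra <- integer(0)
    rb <- integer(0)
    while (length(ra) < n_random) {
      m <- ceiling((n_random - length(ra)) * 1.3) + 10L
      i <- sample.int(n, m, replace = TRUE)
      j <- sample.int(n, m, replace = TRUE)
      ok <- i != j
      lo <- pmin(i[ok], j[ok])
      hi <- pmax(i[ok], j[ok])
      key <- paste(lo, hi)
      fresh <- !(key %in% sis_key) & !duplicated(key) &
        !(key %in% paste(ra, rb))
      ra <- c(ra, lo[fresh])
      rb <- c(rb, hi[fresh])
    }
    ra <- ra[seq_len(n_random)]
    rb <- rb[seq_len(n_random)]
  }

  out <- data.frame(
    cell_a = c(pairs$cell_a, cells[ra]),
    cell_b = c(pairs$cell_b, cells[rb]),
    type = c(rep("sister", nrow(pairs)), rep("random", length(ra))),
    stringsAsFactors = FALSE)
  out$distance <- .pair_dist(mat, match(out$cell_a, cells),
                             match(out$cell_b, cells))
  out
}

#' Remove lowly expressed genes by total-expression quantile
#'
#' Drops genes whose total normalized expression falls below the given
#' quantile of the per-gene total distribution. The cutoff is computed from
#' the data at hand (quantile type 7, R's default linear interpolation);
#' genes tied with the cutoff are kept.
#'
#' @param mat numeric matrix, genes x cells, of normalized values.
#' @param quantile quantile in `[0, 1)` (default 0.10).
#' @return character vector of retained gene names. The realized cutoff is
#'   attached as attribute `"cutoff"`.
#' @export
filter_low_expression_genes <- function(mat, quantile = 0.10) {
  if (quantile < 0 || quantile >= 1) .halt("quantile must lie in [0, 1)")
  totals <- rowSums(mat)
  cutoff <- stats::quantile(totals, quantile, names = FALSE, type = 7)
  keep <- rownames(mat)[totals >= cutoff]
  attr(keep, "cutoff") <- cutoff
  keep
}

#' Remove sister pairs with outlying transcriptomic distance
#'
#' Drops sister pairs whose Euclidean distance exceeds the given quantile of
#' the sister-distance distribution (ties with the cutoff are kept).
#'
#' @param dist_table data.frame from [pair_distances()].
#' @param quantile quantile in `(0, 1]` (default 0.90).
#' @return the sister rows retained, same columns as the input; the realized
#'   cutoff is attached as attribute `"cutoff"`.
#' @export
filter_distant_sisters <- function(dist_table, quantile = 0.90) {
  if (quantile <= 0 || quantile > 1) .halt("quantile must lie in (0, 1]")
  sis <- dist_table[dist_table$type == "sister", , drop = FALSE]
  cutoff <- stats::quantile(sis$distance, quantile, names = FALSE, type = 7)
  out <- sis[sis$distance <= cutoff, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  out
}

# internal: per-gene mean and variance of |log2FC| over a set of pairs,
# streamed in chunks to bound memory
.pair_l2fc_moments <- function(M, a, b, chunk = 5000L) {
  n <- length(a)
  s1 <- numeric(nrow(M))
  s2 <- numeric(nrow(M))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    L <- abs(M[, a[s:e], drop = FALSE] - M[, b[s:e], drop = FALSE])
    s1 <- s1 + rowSums(L)
    s2 <- s2 + rowSums(L * L)
  }
  mean <- s1 / n
  var <- (s2 - n * mean^2) / (n - 1)
  list(mean = mean, var = pmax(var, 0), n = n)
}

#' Sister-concordant genes
#'
#' For each gene, the absolute within-pair log2 fold change
#' `|log2((e_a + p) / (e_b + p))|` (on normalized-then-unlogged expression
#' with pseudocount `p`) is compared between sister pairs and random pairs by
#' a Welch two-sample t-test. Genes whose within-pair fold changes are
#' significantly lower among sisters (BH-adjusted two-tailed P below `alpha`)
#' are flagged concordant, i.e. heritably expressed across one division.
#'
#' @param mat numeric matrix, genes x cells, log-normalized values with
#'   low-expression genes already removed (see
#'   [filter_low_expression_genes()]).
#' @param sister_pairs,random_pairs data.frames with `cell_a`, `cell_b`
#'   (e.g. the two strata of [pair_distances()]).
#' @param alpha FDR threshold (default 0.05).
#' @param pseudocount pseudocount on the unlogged expression scale
#'   (default 1).
#' @return data.frame, one row per gene: mean absolute log2FC in sister and
#'   random pairs, Welch `t`, two-tailed `p`, BH-adjusted `padj`,
#'   `concordant` flag. Zero-variance degenerate genes get `p = 1`.
#' @export
sister_concordant_genes <- function(mat, sister_pairs, random_pairs,
                                    alpha = 0.05, pseudocount = 1) {
  if (nrow(sister_pairs) < 2L || nrow(random_pairs) < 2L) {
    .halt("need at least two sister and two random pairs")
  }
  cells <- colnames(mat)
  M <- log2(expm1(mat) + pseudocount)
  ms <- .pair_l2fc_moments(M, match(sister_pairs$cell_a, cells),
                           match(sister_pairs$cell_b, cells))
  mr <- .pair_l2fc_moments(M, match(random_pairs$cell_a, cells),
                           match(random_pairs$cell_b, cells))
  se2 <- ms$var / ms$n + mr$var / mr$n
  t <- ifelse(se2 > 0, (mr$mean - ms$mean) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((ms$var / ms$n)^2 / (ms$n - 1) +
                        (mr$var / mr$n)^2 / (mr$n - 1)),
               1)
  p <- ifelse(se2 > 0, 2 * pt(-abs(t), df), 1)
  padj <- p.adjust(p, method = "BH")
  data.frame(gene = rownames(mat),
             mean_abs_l2fc_sister = ms$mean,
             mean_abs_l2fc_random = mr$mean,
             t = t, p = p, padj = padj,
             concordant = padj < alpha & ms$mean < mr$mean,
             stringsAsFactors = FALSE)
}
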