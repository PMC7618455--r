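#' QC thresholds for cell filtering
#'
#' Default intervals follow the study design this package models: for
#' pre-treatment samples, total UMI counts in `[20000, 200000]`, detected
#' genes in `[2500, 12000]`; for post-treatment samples `[10000, 100000]` and
#' `[2000, 10000]`; mitochondrial fraction strictly below 0.15 in both.
#' Interval bounds are inclusive; the mitochondrial bound is strict.
#'
#' @param profile `"pre"` or `"post"`, or `"custom"` with explicit bounds.
#' @param umi_range,gene_range inclusive `[low, high]` intervals.
#' @param max_mito_fraction strict upper bound on mitochondrial fraction.
#' @param min_cells_per_gene gene-level expression filter (see
#'   [filter_genes()]).
#' @return object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(profile = c("pre", "post", "custom"),
                          umi_range = NULL, gene_range = NULL,
                          max_mito_fraction = 0.15,
                          min_cells_per_gene = 3L) {
  profile <- match.arg(profile)
  defaults <- switch(profile,
    pre = list(umi = c(20000, 200000), gene = c(2500, 12000)),
    post = list(umi = c(10000, 100000), gene = c(2000, 10000)),
    custom = list(umi = c(0, Inf), gene = c(0, Inf)))
  umi_range <- umi_range %||% defaults$umi
  gene_range <- gene_range %||% defaults$gene
  stopifnot(length(umi_range) == 2L, umi_range[1] <= umi_range[2],
            length(gene_range) == 2L, gene_range[1] <= gene_range[2])
  .check_fraction(max_mito_fraction, "max_mito_fraction")
  structure(list(umi_range = umi_range, gene_range = gene_range,
                 max_mito_fraction = max_mito_fraction,
                 min_cells_per_gene = as.integer(min_cells_per_gene),
                 profile = profile),
            class = "qc_thresholds")
}

#' Attach per-cell QC metrics to a cell matrix
#'
#' Computes total UMI count, detected-gene count and mitochondrial fraction
#' (genes flagged by symbol prefix) into `colData`.
#'
#' @param sce a [SingleCellExperiment::SingleCellExperiment] with a `counts`
#'   assay.
#' @param mito_prefix gene-symbol prefix marking mitochondrial genes
#'   (default `"MT-"`).
#' @return the object with colData columns `total_umis`, `n_genes`,
#'   `mito_fraction`.
#' @export
compute_cell_qc <- function(sce, mito_prefix = "MT-") {
  counts <- SummarizedExperiment::assay(sce, "counts")
  total <- Matrix::colSums(counts)
  ngene <- Matrix::colSums(counts > 0)
  mito <- startsWith(rownames(counts), mito_prefix)
  mito_frac <- if (any(mito)) {
    Matrix::colSums(counts[mito, , drop = FALSE]) / pmax(total, 1)
  } else {
    rep(0, ncol(counts))
  }
  SummarizedExperiment::colData(sce)$total_umis <- as.numeric(total)
  SummarizedExperiment::colData(sce)$n_genes <- as.integer(ngene)
  SummarizedExperiment::colData(sce)$mito_fraction <- as.numeric(mito_frac)
  sce
}

#' Remove genes expressed in too few cells
#'
#' Keeps genes with a positive count in at least `min_cells` cells
#' (default 3, i.e. genes expressed in fewer than three cells are removed).
#'
#' @param sce a [SingleCellExperiment::SingleCellExperiment].
#' @param min_cells minimum number of expressing cells.
#' @return the filtered object.
#' @export
filter_genes <- function(sce, min_cells = 3L) {
  counts <- SummarizedExperiment::assay(sce, "counts")
  keep <- Matrix::rowSums(counts > 0) >= min_cells
  if (!any(keep)) .halt("no gene passes the expression filter")
  sce[keep, ]
}

#' Filter cells on UMI count, gene count and mitochondrial fraction
#'
#' Keeps cells with total UMIs inside `umi_range` (inclusive), detected genes
#' inside `gene_range` (inclusive) and mitochondrial fraction strictly below
#' `max_mito_fraction`. Per-criterion removal counts are attached as the
#' `"removed"` attribute.
#'
#' @param sce a [SingleCellExperiment::SingleCellExperiment]; QC metrics are
#'   computed on the fly if absent.
#' @param thresholds a [qc_thresholds()] object.
#' @param mito_prefix passed to [compute_cell_qc()] when metrics are missing.
#' @return the filtered object, with attribute `removed` (named integer
#'   vector: cells failing each criterion, before intersection).
#' @export
filter_cells <- function(sce, thresholds = qc_thresholds("pre"),
                         mito_prefix = "MT-") {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  cd <- SummarizedExperiment::colData(sce)
  if (is.null(cd$total_umis)) {
    sce <- compute_cell_qc(sce, mito_prefix)
    cd <- SummarizedExperiment::colData(sce)
  }
  ok_umi <- cd$total_umis >= thresholds$umi_range[1] &
    cd$total_umis <= thresholds$umi_range[2]
  ok_gene <- cd$n_genes >= thresholds$gene_range[1] &
    cd$n_genes <= thresholds$gene_range[2]
  ok_mito <- cd$mito_fraction < thresholds$max_mito_fraction
  out <- sce[, ok_umi & ok_gene & ok_mito]
  attr(out, "removed") <- c(umi = sum(!ok_umi), genes = sum(!ok_gene),
                            mito = sum(!ok_mito))
  out
}

#' Log-normalize UMI counts
#'
#' Per cell, `value = ln(1 + count * scale / cell_total)` — the standard
#' library-size normalization with natural-log transform and scale factor
#' 10,000. Zero counts map to zero; the result is stored as the `lognorm`
#' assay.
#'
#' @param sce a [SingleCellExperiment::SingleCellExperiment] with `counts`.
#' @param scale scale factor (default 10000).
#' @return the object with an added `lognorm` assay.
#' @export
normalize_log <- function(sce, scale = 10000) {
  counts <- SummarizedExperiment::assay(sce, "counts")
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) .halt("cell(s) with zero total count; filter first")
  if (methods::is(counts, "CsparseMatrix")) {
    norm <- counts
    norm@x <- log1p(norm@x * scale / rep.int(totals, diff(norm@p)))
  } else {
    norm <- log1p(sweep(as.matrix(counts), 2L, totals, "/") * scale)
  }
  SummarizedExperiment::assay(sce, "lognorm") <- norm
  sce
}

#' Rank genes by variance-stabilized variability and return the top n
#'
#' Standardized-variance selector: fits a loess trend of log10 variance on
#' log10 mean of the raw counts, standardizes each gene's counts by the
#' trend-expected standard deviation, clips standardized values at
#' `sqrt(n_cells)`, and ranks genes by the variance of the clipped values.
#'
#' @param sce a [SingleCellExperiment::SingleCellExperiment] with `counts`.
#' @param n number of genes to return (must not exceed the gene count).
#' @param loess_span span of the mean-variance trend fit (default 0.3).
#' @return character vector of the top `n` gene names, in rank order.
#' @export
top_variable_genes <- function(sce, n = 1000L, loess_span = 0.3) {
  counts <- SummarizedExperiment::assay(sce, "counts")
  if (n > nrow(counts)) .halt("n exceeds the number of genes")
  x <- as.matrix(counts)
  mu <- rowMeans(x)
  v <- apply(x, 1L, var)
  ok <- v > 0 & mu > 0
  std_var <- numeric(nrow(x))
  if (sum(ok) > 10L) {
    fit <- loess(log10(v[ok]) ~ log10(mu[ok]), span = loess_span, degree = 2L)
    exp_sd <- sqrt(10^predict(fit))
    clip <- sqrt(ncol(x))
    z <- (x[ok, , drop = FALSE] - mu[ok]) / exp_sd
    z[z > clip] <- clip
    z[z < -clip] <- -clip
    std_var[ok] <- apply(z, 1L, var)
  } else {
    std_var[ok] <- v[ok]
  }
  ord <- order(-std_var, rownames(x))
  rownames(x)[head(ord, n)]
}
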