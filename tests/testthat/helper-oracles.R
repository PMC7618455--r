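# Independent reference implementations used as oracles, plus small fixture
# builders. These deliberately use naive algorithms (full pairwise matrices,
# exhaustive enumeration, direct running sums) so they share no code with the
# package's implementations.

# brute-force directional clustering: full Hamming matrix + fixed-point
# expansion of each component under the count rule
brute_directional <- function(label_counts) {
  labels <- names(label_counts)
  n <- length(labels)
  cnt <- as.numeric(label_counts)
  if (n == 1L) return(setNames(labels, labels))
  ch <- strsplit(labels, "")
  hd <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sum(ch[[i]] != ch[[j]])
      hd[i, j] <- d
      hd[j, i] <- d
    }
  }
  # directed edge i -> j allowed when Hamming 1 and count rule holds
  edge <- hd == 1L & outer(cnt, cnt, function(a, b) a >= 2 * b - 1)
  ord <- order(-cnt, labels)
  assigned <- rep(NA_integer_, n)
  for (seed in ord) {
    if (!is.na(assigned[seed])) next
    members <- seed
    repeat {
      reach <- which(is.na(assigned) & !(seq_len(n) %in% members) &
                     apply(edge[members, , drop = FALSE], 2L, any))
      if (!length(reach)) break
      members <- c(members, reach[1L])
    }
    assigned[members] <- seed
  }
  setNames(labels[assigned], labels)
}

# exact two-sided rank-sum P by enumeration of all group assignments
exact_ranksum_p <- function(x, y) {
  all_v <- c(x, y)
  na <- length(x)
  r <- rank(all_v)
  w_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- combn(length(all_v), na)
  w_all <- apply(combos, 2L, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  pl <- mean(w_all <= w_obs)
  pu <- mean(w_all >= w_obs)
  min(1, 2 * min(pl, pu))
}

# direct running-sum GSEA enrichment score (full cumulative walk)
brute_es <- function(w, pos) {
  N <- length(w)
  hit <- seq_len(N) %in% pos
  nr <- sum(w[hit])
  if (nr == 0 || all(hit) || !any(hit)) return(0)
  step <- ifelse(hit, w / nr, -1 / (N - sum(hit)))
  run <- cumsum(step)
  run[which.max(abs(run))]
}

# area under the ROC curve via the rank-sum identity
auroc <- function(score, is_positive) {
  r <- rank(score)
  n1 <- sum(is_positive)
  n0 <- sum(!is_positive)
  (sum(r[is_positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# small SingleCellExperiment from a dense count matrix
make_test_sce <- function(counts, sample = "s1") {
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("G", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("c", seq_len(ncol(counts)))
  }
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = Matrix::Matrix(counts, sparse = TRUE)),
    colData = S4Vectors::DataFrame(
      cell_id = colnames(counts),
      sample = rep_len(sample, ncol(counts)),
      row.names = colnames(counts)))
}

# random 20-mer labels at controlled pairwise relationships
random_labels <- function(n, len = 20L) {
  vapply(seq_len(n), function(i) {
    paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, "")
}

# mutate one position of a label
mutate_label <- function(label, pos = 1L) {
  ch <- strsplit(label, "")[[1]]
  ch[pos] <- setdiff(c("A", "C", "G", "T"), ch[pos])[1L]
  paste0(ch, collapse = "")
}

# build one cell column with an exact total, detected-gene count and
# mitochondrial count (gene 1 is "MT-1")
.qc_cell <- function(total, n_det, mito) {
  rest <- total - mito
  k <- n_det - 1L                     # non-mito detected genes
  base <- rest %/% k
  extra <- rest %% k
  counts <- rep(base, k)
  counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
  c(mito, counts)
}

# 20-cell QC fixture; specs = list of c(total, n_detected, mito_count)
.qc_fixture <- function(specs, n_genes = 13000L) {
  cells <- lapply(specs, function(s) .qc_cell(s[1], s[2], s[3]))
  i <- unlist(lapply(cells, function(v) seq_along(v)))
  j <- rep(seq_along(cells), lengths(cells))
  x <- unlist(cells)
  m <- Matrix::sparseMatrix(i = i, j = j, x = x,
                            dims = c(n_genes, length(cells)))
  rownames(m) <- c("MT-1", paste0("G", seq_len(n_genes - 1L)))
  colnames(m) <- paste0("cell", seq_along(cells))
  make_test_sce(m)
}
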