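#' Write a cell matrix to disk
#'
#' `format = "mtx"` writes the MatrixMarket triplet (`matrix.mtx`,
#' `features.tsv`, `barcodes.tsv`) plus `metadata.tsv`; `format = "tsv"`
#' writes a dense genes x cells table plus `metadata.tsv`.
#'
#' @param sce a [SingleCellExperiment::SingleCellExperiment] with `counts`.
#' @param dir output directory (created if needed).
#' @param format `"mtx"` or `"tsv"`.
#' @return `dir`, invisibly.
#' @export
write_cell_matrix <- function(sce, dir, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- SummarizedExperiment::assay(sce, "counts")
  meta <- as.data.frame(SummarizedExperiment::colData(sce))
  if (format == "mtx") {
    Matrix::writeMM(methods::as(counts, "CsparseMatrix"),
                    file.path(dir, "matrix.mtx"))
    writeLines(rownames(counts), file.path(dir, "features.tsv"))
    writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  } else {
    write.table(as.matrix(counts), file.path(dir, "counts.tsv"),
                sep = "\t", quote = FALSE, col.names = NA)
  }
  write.table(meta, file.path(dir, "metadata.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a cell matrix written by [write_cell_matrix()]
#'
#' @param dir directory containing the files.
#' @return a [SingleCellExperiment::SingleCellExperiment].
#' @export
read_cell_matrix <- function(dir) {
  meta <- read.delim(file.path(dir, "metadata.tsv"),
                     stringsAsFactors = FALSE)
  if (file.exists(file.path(dir, "matrix.mtx"))) {
    counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                          "CsparseMatrix")
    rownames(counts) <- readLines(file.path(dir, "features.tsv"))
    colnames(counts) <- readLines(file.path(dir, "barcodes.tsv"))
  } else {
    tab <- read.delim(file.path(dir, "counts.tsv"), row.names = 1L,
                      check.names = FALSE)
    counts <- Matrix::Matrix(as.matrix(tab), sparse = TRUE)
  }
  .make_sce(counts, meta)
}

#' Write / read a cell-to-label table
#'
#' TSV with columns `cell_id`, `sample` (optional), `label`.
#'
#' @param labels named character vector (names = cell ids).
#' @param path file path.
#' @param sample optional sample id(s), recycled.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(labels, path, sample = NULL) {
  df <- data.frame(cell_id = names(labels), label = unname(labels),
                   stringsAsFactors = FALSE)
  if (!is.null(sample)) df$sample <- rep_len(sample, nrow(df))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  setNames(df$label, df$cell_id)
}

#' Write / read a dose-response matrix as long-format CSV
#'
#' Long format with a controls header: comment lines `# neg_ctrl=...` /
#' `# pos_ctrl=...`, then columns `drug1_dose`, `drug2_dose`, `replicate`,
#' `reading`.
#'
#' @param drm a [dose_response_matrix()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_dose_response_csv <- function(drm, path) {
  stopifnot(inherits(drm, "dose_response_matrix"))
  dims <- dim(drm$readings)
  grid <- expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                      r = seq_len(dims[3]))
  df <- data.frame(drug1_dose = drm$doses1[grid$i],
                   drug2_dose = drm$doses2[grid$j],
                   replicate = grid$r,
                   reading = drm$readings[cbind(grid$i, grid$j, grid$r)])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# neg_ctrl=%.10g", drm$neg_ctrl),
               sprintf("# pos_ctrl=%.10g", drm$pos_ctrl)), con)
  write.table(df, con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dose_response_csv
#' @export
read_dose_response_csv <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  get_ctrl <- function(key) {
    line <- grep(paste0("^# *", key, "="), hdr, value = TRUE)
    if (!length(line)) .halt("missing '", key, "' header in ", path)
    as.numeric(sub(".*=", "", line[1]))
  }
  df <- read.csv(path, comment.char = "#")
  doses1 <- sort(unique(df$drug1_dose))
  doses2 <- sort(unique(df$drug2_dose))
  reps <- sort(unique(df$replicate))
  readings <- array(NA_real_, c(length(doses1), length(doses2), length(reps)))
  readings[cbind(match(df$drug1_dose, doses1), match(df$drug2_dose, doses2),
                 match(df$replicate, reps))] <- df$reading
  dose_response_matrix(doses1, doses2, readings,
                       neg_ctrl = get_ctrl("neg_ctrl"),
                       pos_ctrl = get_ctrl("pos_ctrl"))
}

#' Write simulation ground truth as JSON
#'
#' @param truth the `truth` element of [simulate_experiment()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  out <- truth
  out$config <- unclass(out$config)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
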