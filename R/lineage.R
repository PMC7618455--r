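#' Partition pre-treatment cells into fate classes
#'
#' A pre-treatment cell whose lineage label is detected among the
#' corresponding post-treatment survivors is pre-resistant (pre-fit in the
#' vehicle-control arm); a cell whose lineage is not detected after treatment
#' is pre-sensitive (pre-unfit). Presence is a set-membership test on
#' corrected labels; labels seen only post-treatment are ignored.
#'
#' @param pre_labels named character vector: label per pre-treatment cell id.
#' @param post_labels character vector of labels detected in the matching
#'   post-treatment sample (duplicates allowed; used as a set).
#' @param arm `"treatment"` (classes pre_resistant / pre_sensitive) or
#'   `"control"` (pre_fit / pre_unfit).
#' @return object of class `fate_partition`: list with `cells` (data.frame
#'   `cell_id`, `label`, `fate`), `lineages` (data.frame `label`,
#'   `n_pre_cells`, `in_post`, `fate`) and `arm`.
#' @export
assign_fates <- function(pre_labels, post_labels,
                         arm = c("treatment", "control")) {
  arm <- match.arg(arm)
  pre_labels <- pre_labels[!is.na(pre_labels)]
  if (!length(pre_labels)) .halt("no labeled pre-treatment cells")
  classes <- if (arm == "treatment") {
    c(hit = "pre_resistant", miss = "pre_sensitive")
  } else {
    c(hit = "pre_fit", miss = "pre_unfit")
  }
  post_set <- unique(post_labels[!is.na(post_labels)])
  in_post <- pre_labels %in% post_set
  cells <- data.frame(cell_id = names(pre_labels),
                      label = unname(pre_labels),
                      fate = ifelse(in_post, classes[["hit"]], classes[["miss"]]),
                      stringsAsFactors = FALSE)
  tab <- table(pre_labels)
  lineages <- data.frame(label = names(tab),
                         n_pre_cells = as.integer(tab),
                         in_post = names(tab) %in% post_set,
                         stringsAsFactors = FALSE)
  lineages$fate <- ifelse(lineages$in_post, classes[["hit"]], classes[["miss"]])
  structure(list(cells = cells, lineages = lineages, arm = arm),
            class = "fate_partition")
}

#' @export
print.fate_partition <- function(x, ...) {
  cat("fate_partition (", x$arm, " arm): ", nrow(x$cells), " cells, ",
      nrow(x$lineages), " lineages\n", sep = "")
  print(table(x$cells$fate))
  invisible(x)
}

#' Cells lacking sisters in the same pre-treatment sample
#'
#' Returns the cells whose lineage label occurs exactly once in that sample.
#' Downstream differential expression uses only these singleton-lineage cells,
#' to exclude lineages with elevated basal growth and to avoid
#' false-negatives from both sisters landing in the profiled half.
#'
#' @param pre_labels named character vector: label per pre-treatment cell id.
#' @return character vector of cell ids.
#' @export
singleton_cells <- function(pre_labels) {
  pre_labels <- pre_labels[!is.na(pre_labels)]
  tab <- table(pre_labels)
  names(pre_labels)[pre_labels %in% names(tab)[tab == 1L]]
}

#' Enumerate sister-cell pairs
#'
#' Sister cells are distinct cells sharing one lineage label within a
#' treatment group. When `sample` is given, pairs are formed only within the
#' same sample. For the concordance analysis, only lineages with exactly two
#' cells are used (`restrict_two = TRUE`).
#'
#' @param cell_labels named character vector: label per cell id.
#' @param sample optional named character vector (or vector parallel to
#'   `cell_labels`) giving each cell's sample; pairs never span samples.
#' @param restrict_two keep only lineages with exactly two cells
#'   (default TRUE); otherwise all unordered pairs of a lineage are emitted.
#' @return data.frame with columns `cell_a`, `cell_b`, `label`.
#' @export
sister_pairs <- function(cell_labels, sample = NULL, restrict_two = TRUE) {
  cell_labels <- cell_labels[!is.na(cell_labels)]
  if (!length(cell_labels)) {
    return(data.frame(cell_a = character(0), cell_b = character(0),
                      label = character(0), stringsAsFactors = FALSE))
  }
  grp <- if (is.null(sample)) {
    unname(cell_labels)
  } else {
    s <- if (!is.null(names(sample))) sample[names(cell_labels)] else sample
    paste(s, cell_labels, sep = "\t")
  }
  bylab <- split(names(cell_labels), grp)
  sizes <- lengths(bylab)
  bylab <- if (restrict_two) bylab[sizes == 2L] else bylab[sizes >= 2L]
  if (!length(bylab)) {
    return(data.frame(cell_a = character(0), cell_b = character(0),
                      label = character(0), stringsAsFactors = FALSE))
  }
  out <- lapply(names(bylab), function(k) {
    cells <- sort(bylab[[k]])
    cmb <- combn(cells, 2L)
    data.frame(cell_a = cmb[1L, ], cell_b = cmb[2L, ],
               label = unname(cell_labels[cmb[1L, ]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
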