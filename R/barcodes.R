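#' Barcode template with anchor dinucleotides
#'
#' The expressed lineage barcode consists of five blocks of four informative
#' (random) bases separated by fixed anchor dinucleotides; the default
#' sub-pattern is `CANNNNTGNNNNACNNNNGANNNNGTNNNNCT`. Matching a read against
#' the template and concatenating the informative positions yields the 20-base
#' lineage label.
#'
#' @param pattern template string; `N` marks informative positions.
#' @return object of class `barcode_template` with fields `pattern`,
#'   `informative_positions` and a compiled regular expression.
#' @export
barcode_template <- function(pattern = .BARCODE_SUBPATTERN) {
  chars <- strsplit(pattern, "")[[1]]
  if (!all(chars %in% c("A", "C", "G", "T", "N"))) {
    .halt("template pattern must be over {A,C,G,T,N}")
  }
  pos <- which(chars == "N")
  regex <- paste0(ifelse(chars == "N", "[ACGT]", chars), collapse = "")
  structure(list(pattern = pattern,
                 informative_positions = pos,
                 regex = regex),
            class = "barcode_template")
}

# internal: reverse complement of DNA strings
.revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, ""), function(s) paste0(rev(s), collapse = ""), "")
}

#' Extract 20-base lineage labels from read sequences
#'
#' Finds the first exact occurrence of the template anchors in each read and
#' returns the concatenated informative bases (20 per read for the default
#' template). Reads without an anchor match return `NA`; the reverse
#' complement is searched when the forward orientation fails. Reads containing
#' characters outside `{A,C,G,T,N}` are rejected with a warning.
#'
#' @param reads character vector of upper-case DNA reads.
#' @param template a [barcode_template()].
#' @param search_revcomp also search the reverse complement (default TRUE).
#' @return character vector of labels (`NA` = no match), same length as
#'   `reads`.
#' @export
extract_label <- function(reads, template = barcode_template(),
                          search_revcomp = TRUE) {
  stopifnot(inherits(template, "barcode_template"))
  out <- rep(NA_character_, length(reads))
  bad <- grepl("[^ACGTN]", reads)
  if (any(bad)) {
    warning(sum(bad), " read(s) contain non-ACGTN characters; rejected")
  }
  ok <- !bad
  hit <- rep(-1L, length(reads))
  hit[ok] <- regexpr(template$regex, reads[ok])
  fwd <- hit > 0L
  if (any(fwd)) {
    out[fwd] <- .pull_informative(reads[fwd], hit[fwd], template)
  }
  if (search_revcomp) {
    miss <- ok & !fwd
    if (any(miss)) {
      rc <- .revcomp(reads[miss])
      hit2 <- regexpr(template$regex, rc)
      got <- hit2 > 0L
      if (any(got)) {
        idx <- which(miss)[got]
        out[idx] <- .pull_informative(rc[got], hit2[got], template)
      }
    }
  }
  out
}

# internal: concatenate the informative positions of a matched window
.pull_informative <- function(reads, start, template) {
  pos <- template$informative_positions
  mat <- vapply(seq_along(pos), function(k) {
    substring(reads, start + pos[k] - 1L, start + pos[k] - 1L)
  }, character(length(reads)))
  if (length(reads) == 1L) mat <- matrix(mat, nrow = 1L)
  apply(mat, 1L, paste0, collapse = "")
}

# internal: candidate Hamming-distance-1 pairs among equal-length strings,
# found by hashing each string 'length' times with one position masked
.hamming1_pairs <- function(labels) {
  L <- nchar(labels[1])
  n <- length(labels)
  pairs_a <- integer(0)
  pairs_b <- integer(0)
  for (p in seq_len(L)) {
    key <- paste0(substr(labels, 1L, p - 1L), ".", substr(labels, p + 1L, L))
    grp <- split(seq_len(n), key)
    grp <- grp[lengths(grp) > 1L]
    for (g in grp) {
      cmb <- combn(g, 2L)
      pairs_a <- c(pairs_a, cmb[1L, ])
      pairs_b <- c(pairs_b, cmb[2L, ])
    }
  }
  unique(cbind(pairs_a, pairs_b))
}

#' Directional error correction of lineage labels
#'
#' Implements the directional network method for barcode/UMI error
#' correction: a directed edge runs from label `a` to label `b` when they
#' differ at exactly one position and `count(a) >= 2 * count(b) - 1`.
#' Components are grown from the highest-count unassigned label by following
#' directional edges transitively, and every member collapses to its
#' component's seed (the highest-count label; count ties broken
#' lexicographically). The returned mapping is idempotent.
#'
#' @param label_counts named numeric vector: total read count per raw label.
#' @return named character vector mapping each raw label to its corrected
#'   label.
#' @export
correct_directional <- function(label_counts) {
  if (!length(label_counts)) .halt("label_counts is empty")
  if (any(label_counts <= 0)) .halt("counts must be positive")
  labels <- names(label_counts)
  if (is.null(labels) || anyDuplicated(labels)) {
    .halt("label_counts must be uniquely named by label")
  }
  if (length(unique(nchar(labels))) != 1L) {
    .halt("labels must all have the same length")
  }
  n <- length(labels)
  counts <- as.numeric(label_counts)
  ord <- order(-counts, labels)

  if (n == 1L) return(setNames(labels, labels))

  ep <- .hamming1_pairs(labels)
  adj <- vector("list", n)
  if (nrow(ep)) {
    for (k in seq_len(nrow(ep))) {
      a <- ep[k, 1L]; b <- ep[k, 2L]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }

  assigned <- integer(n)   # 0 = unassigned, else index of component seed
  for (seed in ord) {
    if (assigned[seed]) next
    assigned[seed] <- seed
    queue <- seed
    while (length(queue)) {
      u <- queue[[1L]]
      queue <- queue[-1L]
      for (v in adj[[u]]) {
        if (!assigned[v] && counts[u] >= 2 * counts[v] - 1) {
          assigned[v] <- seed
          queue <- c(queue, v)
        }
      }
    }
  }
  setNames(labels[assigned], labels)
}

#' Assign a consensus lineage label to each cell
#'
#' Per cell, picks the corrected label with the highest total read count.
#' Cells whose top two labels tie, or whose best label has fewer than
#' `min_reads` reads, are marked unlabeled (`NA`).
#'
#' @param label_table data.frame with columns `cell_id`, `label` and
#'   optionally `count` (default 1 per row), where `label` is already
#'   error-corrected.
#' @param min_reads minimum read support for the winning label (default 1).
#' @return data.frame with columns `cell_id`, `label` (`NA` = unlabeled),
#'   `n_reads` (support for the winning label).
#' @export
assign_cell_labels <- function(label_table, min_reads = 1L) {
  stopifnot(all(c("cell_id", "label") %in% names(label_table)))
  if (is.null(label_table$count)) label_table$count <- 1L
  # re-aggregate (several raw labels may share a corrected label)
  key <- paste(label_table$cell_id, label_table$label, sep = "\t")
  cnt <- rowsum(as.numeric(label_table$count), key)
  parts <- strsplit(rownames(cnt), "\t", fixed = TRUE)
  tab <- data.frame(cell_id = vapply(parts, `[[`, "", 1L),
                    label = vapply(parts, `[[`, "", 2L),
                    count = as.numeric(cnt[, 1L]),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$cell_id, -tab$count, tab$label), , drop = FALSE]
  first <- !duplicated(tab$cell_id)
  top <- tab[first, , drop = FALSE]
  nxt <- which(first) + 1L
  has2 <- nxt <= nrow(tab) & tab$cell_id[pmin(nxt, nrow(tab))] == top$cell_id
  second <- ifelse(has2, tab$count[pmin(nxt, nrow(tab))], -Inf)
  tie <- second == top$count
  out <- data.frame(cell_id = top$cell_id,
                    label = ifelse(tie | top$count < min_reads,
                                   NA_character_, top$label),
                    n_reads = top$count,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Remove promiscuous labels shared by too many cells
#'
#' Drops every cell carrying a label observed in more than `max_cells` cells
#' of the same pre-treatment sample (default: more than four cells), since
#' such labels cannot identify a single lineage.
#'
#' @param cell_labels named character vector: label per cell id (one
#'   pre-treatment sample).
#' @param max_cells maximum number of cells a label may appear in (default 4).
#' @return list with `labels` (filtered named vector) and `removed`
#'   (data.frame of dropped labels with their cell counts).
#' @export
filter_shared_labels <- function(cell_labels, max_cells = 4L) {
  cell_labels <- cell_labels[!is.na(cell_labels)]
  tab <- table(cell_labels)
  bad <- names(tab)[tab > max_cells]
  keep <- !(cell_labels %in% bad)
  list(labels = cell_labels[keep],
       removed = data.frame(label = bad,
                            n_cells = as.integer(tab[bad]),
                            stringsAsFactors = FALSE))
}

#' Tabulate read counts per (cell, extracted label)
#'
#' Convenience step between [extract_label()] and [correct_directional()] /
#' [assign_cell_labels()].
#'
#' @param cell_id character vector of cell ids, parallel to `labels`.
#' @param labels character vector of extracted raw labels (`NA` dropped).
#' @return data.frame with columns `cell_id`, `label`, `count`.
#' @export
label_count_table <- function(cell_id, labels) {
  keep <- !is.na(labels)
  key <- paste(cell_id[keep], labels[keep], sep = "\t")
  cnt <- rowsum(rep(1, sum(keep)), key)
  parts <- strsplit(rownames(cnt), "\t", fixed = TRUE)
  out <- data.frame(cell_id = vapply(parts, `[[`, "", 1L),
                    label = vapply(parts, `[[`, "", 2L),
                    count = as.numeric(cnt[, 1L]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$cell_id, -out$count), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full barcode-processing chain on raw reads
#'
#' Extract labels, correct errors at the sample level with the directional
#' method, assign per-cell consensus labels, and drop labels shared by more
#' than `max_shared` cells.
#'
#' @param reads data.frame with columns `cell_id`, `read`.
#' @param template a [barcode_template()].
#' @param min_reads per-cell minimum read support.
#' @param max_shared promiscuous-label cutoff (cells per label).
#' @param correct apply directional correction (default TRUE).
#' @return list with `labels` (named vector cell -> label), `removed`
#'   (promiscuous-label report), `cell_table` (per-cell assignment table) and
#'   `correction_map` (raw -> corrected label map).
#' @export
process_reads <- function(reads, template = barcode_template(),
                          min_reads = 1L, max_shared = 4L, correct = TRUE) {
  stopifnot(all(c("cell_id", "read") %in% names(reads)))
  raw <- extract_label(reads$read, template)
  tab <- label_count_table(reads$cell_id, raw)
  if (!nrow(tab)) .halt("no read matched the barcode template")
  totals <- tapply(tab$count, tab$label, sum)
  map <- if (correct) {
    correct_directional(setNames(as.numeric(totals), names(totals)))
  } else {
    setNames(names(totals), names(totals))
  }
  tab$label <- unname(map[tab$label])
  cells <- assign_cell_labels(tab, min_reads = min_reads)
  labeled <- setNames(cells$label, cells$cell_id)
  shared <- filter_shared_labels(labeled, max_cells = max_shared)
  list(labels = shared$labels, removed = shared$removed,
       cell_table = cells, correction_map = map)
}
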