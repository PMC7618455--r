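# internal: weighted Kolmogorov-Smirnov enrichment score of a hit set against
# a ranked profile. `w` = |rank statistic|^exponent in rank order; `pos` =
# hit positions (ascending). Returns the signed maximum deviation of the
# running sum (GSEA-style), evaluated at the peak after and the trough before
# each hit.
.es_from_pos <- function(w, pos) {
  N <- length(w)
  Nh <- length(pos)
  if (Nh == 0L || Nh == N) return(0)
  pos <- sort(pos)
  wr <- w[pos]
  NR <- sum(wr)
  if (NR == 0) return(0)   # degenerate flat profile
  miss_unit <- 1 / (N - Nh)
  cum_hit <- cumsum(wr) / NR
  j <- seq_len(Nh)
  peak <- cum_hit - (pos - j) * miss_unit
  trough <- c(0, cum_hit[-Nh]) - (pos - 1 - (j - 1)) * miss_unit
  hi <- max(peak)
  lo <- min(trough)
  if (hi >= -lo) hi else lo
}

#' Connectivity score of a query signature against a drug profile
#'
#' Connectivity-Map style score: the query is split into an up set
#' (`log2FC > 0`) and a down set (`log2FC < 0`); weighted KS enrichment
#' scores of each set are computed against the drug's gene ranking, and the
#' score is `(ES_up - ES_down) / 2` when the two enrichment scores have
#' opposite signs, else exactly 0. A negative score means the drug reverses
#' the query signature. Significance comes from permuting the gene labels of
#' the drug profile.
#'
#' @param query named numeric vector of per-gene query weights (log2FC).
#' @param profile named numeric vector: the drug's differential-expression
#'   profile (e.g. consensus z-scores); only its ranking matters.
#' @param n_perm permutation count (default 1000).
#' @param seed integer seed.
#' @param min_overlap minimum genes shared between query and profile
#'   (default 10).
#' @param exponent enrichment weighting exponent on the |rank statistic|
#'   (default 1).
#' @return list with `score` (in `[-1, 1]`), `p` (permutation P with +1
#'   correction), `es_up`, `es_down`, `n_overlap`.
#' @export
connectivity_score <- function(query, profile, n_perm = 1000L, seed = 1L,
                               min_overlap = 10L, exponent = 1) {
  profile <- profile[!is.na(profile)]
  shared <- intersect(names(query), names(profile))
  if (length(shared) < min_overlap) {
    .halt("only ", length(shared), " genes shared between query and profile",
          " (min_overlap = ", min_overlap, ")")
  }
  q <- query[shared]
  ord <- order(profile, decreasing = TRUE)
  ranked <- names(profile)[ord]
  w <- abs(profile[ord])^exponent
  up <- names(q)[q > 0]
  down <- names(q)[q < 0]
  pos_up <- match(up, ranked)
  pos_down <- match(down, ranked)
  es_up <- .es_from_pos(w, pos_up)
  es_down <- .es_from_pos(w, pos_down)
  combine <- function(eu, ed) if (sign(eu) == sign(ed)) 0 else (eu - ed) / 2
  score <- combine(es_up, es_down)

  set.seed(seed)
  N <- length(ranked)
  nu <- length(pos_up)
  nd <- length(pos_down)
  perm <- vapply(seq_len(n_perm), function(k) {
    idx <- sample.int(N, nu + nd)
    combine(.es_from_pos(w, idx[seq_len(nu)]),
            .es_from_pos(w, idx[nu + seq_len(nd)]))
  }, numeric(1))
  p <- (1 + sum(abs(perm) >= abs(score))) / (n_perm + 1)
  list(score = unname(score), p = p, es_up = unname(es_up),
       es_down = unname(es_down), n_overlap = length(shared))
}

#' Score every drug in a library against every signature variant
#'
#' @param variants a `signature_variants` object (or named list of query
#'   weight vectors).
#' @param library numeric matrix, drugs x genes, of drug-induced
#'   differential-expression weights; `NA` entries are dropped per drug.
#' @param n_perm,seed,min_overlap,exponent passed to [connectivity_score()].
#' @return data.frame with columns `drug`, `variant`, `score`, `p`.
#' @export
connectivity_table <- function(variants, library, n_perm = 1000L, seed = 1L,
                               min_overlap = 10L, exponent = 1) {
  stopifnot(is.matrix(library), !is.null(rownames(library)),
            !is.null(colnames(library)))
  all_na <- apply(library, 1L, function(x) all(is.na(x)))
  if (any(all_na)) .halt("drug row(s) with no values: ",
                         paste(head(rownames(library)[all_na], 3), collapse = ", "))
  rows <- list()
  k <- 0L
  for (drug in rownames(library)) {
    prof <- library[drug, ]
    for (v in names(variants)) {
      k <- k + 1L
      cs <- connectivity_score(variants[[v]], prof, n_perm = n_perm,
                               seed = seed + k, min_overlap = min_overlap,
                               exponent = exponent)
      rows[[k]] <- data.frame(drug = drug, variant = v, score = cs$score,
                              p = cs$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank drugs and apply the all-variants significance filter
#'
#' Drugs are sorted ascending by their mean connectivity score across the
#' signature variants (most strongly signature-reversing first); a drug
#' passes iff its score is negative with `P < alpha` in every variant.
#'
#' @param tbl output of [connectivity_table()].
#' @param alpha per-variant significance level (default 0.05).
#' @return data.frame, one row per drug, sorted ascending by `mean_score`,
#'   with `n_variants`, `n_pass` and logical `pass`.
#' @export
rank_and_filter <- function(tbl, alpha = 0.05) {
  sp <- split(tbl, tbl$drug)
  out <- do.call(rbind, lapply(sp, function(d) {
    ok <- d$score < 0 & d$p < alpha
    data.frame(drug = d$drug[1L],
               mean_score = mean(d$score),
               n_variants = nrow(d),
               n_pass = sum(ok),
               pass = all(ok),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$mean_score), , drop = FALSE]
  rownames(out) <- NULL
  out
}
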