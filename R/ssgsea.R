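#' Per-sample descending expression ranks
#'
#' Within each sample, genes are ranked descending by expression (rank 1 =
#' highest). Ties are broken deterministically by ascending lexicographic
#' gene-id order, so a constant sample ranks entirely by id.
#'
#' @param expr Numeric genes-by-samples matrix with gene rownames.
#' @return Integer matrix of the same shape: rank of each gene in each sample.
#' @export
rank_normalize <- function(expr) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  if (anyNA(expr)) stop("missing values in expression matrix")
  id_order <- order(rownames(expr))  # ascending id = tie winner
  out <- matrix(0L, nrow(expr), ncol(expr), dimnames = dimnames(expr))
  for (j in seq_len(ncol(expr))) {
    # order by decreasing value, ties resolved by position in id_order
    ord <- id_order[order(expr[id_order, j], decreasing = TRUE)]
    out[ord, j] <- seq_len(nrow(expr))
  }
  out
}

#' Single-sample GSEA (ssGSEA) enrichment score
#'
#' Rank-based running-sum enrichment of a gene set within each sample,
#' following the GenePattern ssGSEA projection: genes are ordered by
#' decreasing expression; the in-set cumulative distribution accumulates
#' rank weights raised to `alpha` (normalized to 1), the out-of-set
#' distribution accumulates uniform mass; the score is the sum of their
#' differences over all positions. The rank weight of the gene at position
#' i (of N) is N - i + 1, so scores depend only on within-sample ordering
#' and are invariant under strictly monotone transforms of the expression
#' values.
#'
#' Set genes absent from the matrix are dropped with a warning. When the set
#' covers every gene the out-of-set distribution is empty and is defined as
#' identically zero, giving the maximal positive score.
#'
#' @param expr Numeric genes-by-samples matrix with gene rownames.
#' @param set Character vector of gene ids.
#' @param alpha Rank weight exponent (GenePattern default 0.25).
#' @return Named numeric vector of per-sample enrichment scores.
#' @export
ssgsea_score <- function(expr, set, alpha = 0.25) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  set <- unique(as.character(set))
  present <- set %in% rownames(expr)
  if (!all(present)) {
    warning(sprintf("%d of %d set genes absent from matrix; dropped",
                    sum(!present), length(set)))
    set <- set[present]
  }
  if (length(set) == 0L) stop("no set gene present in expression matrix")
  n <- nrow(expr)
  ranks <- rank_normalize(expr)
  in_set <- rownames(expr) %in% set
  n_out <- n - sum(in_set)
  scores <- numeric(ncol(expr))
  for (j in seq_len(ncol(expr))) {
    pos <- ranks[, j]                       # position of each gene, 1 = top
    ord <- order(pos)                       # genes in descending expression
    hit <- in_set[ord]
    w <- (n - seq_len(n) + 1)^alpha         # rank weight at each position
    w[!hit] <- 0
    p_in <- cumsum(w) / sum(w)
    p_out <- if (n_out == 0L) rep(0, n) else cumsum(!hit) / n_out
    scores[j] <- sum(p_in - p_out)
  }
  names(scores) <- colnames(expr)
  scores
}

#' Combined UP-minus-DN enrichment score
#'
#' The combined activation score is the elementwise difference of the UP and
#' DN set scores over the same samples.
#'
#' @param es_up Named per-sample scores for the UP set.
#' @param es_dn Named per-sample scores for the DN set (same samples).
#' @return Named numeric vector `es_up - es_dn`.
#' @export
combined_score <- function(es_up, es_dn) {
  if (length(es_up) != length(es_dn)) stop("sample sets differ in length")
  if (!is.null(names(es_up)) || !is.null(names(es_dn))) {
    if (is.null(names(es_up)) || is.null(names(es_dn)) ||
        !setequal(names(es_up), names(es_dn))) {
      stop("sample names of UP and DN scores do not match")
    }
    es_dn <- es_dn[names(es_up)]
  }
  es_up - es_dn
}

#' Score a cohort with a paired UP/DN signature
#'
#' Convenience wrapper returning per-sample `es_up`, `es_dn` and
#' `es_combined = es_up - es_dn`.
#'
#' @param expr Numeric genes-by-samples matrix.
#' @param sig A `SignaturePair` (see [build_signature()]).
#' @param alpha Rank weight exponent passed to [ssgsea_score()].
#' @return data.frame with columns `sample`, `es_up`, `es_dn`, `es_combined`.
#' @export
score_signature <- function(expr, sig, alpha = 0.25) {
  up <- ssgsea_score(expr, sig$up, alpha = alpha)
  dn <- ssgsea_score(expr, sig$dn, alpha = alpha)
  data.frame(sample = colnames(expr), es_up = unname(up), es_dn = unname(dn),
             es_combined = unname(combined_score(up, dn)),
             stringsAsFactors = FALSE)
}
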