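#' Pair mouse CNA-positive regions with their human homologues
#'
#' Region keys are `chrom:start-end`. A mouse region may map to several
#' human regions (one output pair per mapping); mouse regions with no entry
#' in the homology map are reported unmapped.
#'
#' @param mouse A `CNARegionSet` of mouse CNA calls.
#' @param map data.frame with columns `mouse_key`, `human_key`.
#' @param human A `CNARegionSet` of human regions (keys must resolve).
#' @return list with `pairs` (data.frame `mouse_key`, `human_key`,
#'   `cna_type`, `human_frequency`) and `unmapped` (character vector of
#'   mouse keys).
#' @export
map_homologues <- function(mouse, map, human) {
  stopifnot(all(c("mouse_key", "human_key") %in% names(map)))
  mkey <- region_key(mouse)
  hkey <- region_key(human)
  dangling <- setdiff(map$human_key, hkey)
  if (length(dangling)) {
    stop("homology map references unknown human region(s): ",
         paste(utils::head(dangling, 5), collapse = ", "))
  }
  dangling_m <- setdiff(map$mouse_key, mkey)
  if (length(dangling_m)) {
    stop("homology map references unknown mouse region(s): ",
         paste(utils::head(dangling_m, 5), collapse = ", "))
  }
  hits <- map[map$mouse_key %in% mkey, , drop = FALSE]
  mi <- match(hits$mouse_key, mkey)
  hi <- match(hits$human_key, hkey)
  freq <- if ("frequency" %in% names(human)) human$frequency[hi] else
    rep(NA_real_, length(hi))
  pairs <- data.frame(mouse_key = hits$mouse_key, human_key = hits$human_key,
                      cna_type = mouse$cna_type[mi],
                      human_cna_type = human$cna_type[hi],
                      human_frequency = freq,
                      stringsAsFactors = FALSE)
  list(pairs = pairs, unmapped = setdiff(mkey, map$mouse_key))
}

#' Canonical region keys (`chrom:start-end`)
#'
#' @param regions A `CNARegionSet` data.frame.
#' @return Character vector of keys.
#' @export
region_key <- function(regions) {
  paste0(regions$chrom, ":", regions$start, "-", regions$end)
}

#' Concordance contingency table for one CNA type
#'
#' A mouse-human pair is concordant when the human same-type carrier
#' frequency strictly exceeds the threshold ("exceeded" is strict; a
#' frequency exactly at the threshold is not concordant; an absent
#' frequency counts as 0). The 2x2 table contrasts the CNA-type pairs with
#' a caller-supplied background pair set subjected to the same rule.
#'
#' @param pairs data.frame with columns `cna_type`, `human_cna_type`,
#'   `human_frequency` (e.g. from [map_homologues()]).
#' @param background data.frame with the same columns, the comparison
#'   stratum.
#' @param cna_type `"gain"` or `"loss"`; rows of `pairs` of this type enter
#'   the first row of the table.
#' @param threshold Human carrier-frequency threshold (default 0.05).
#' @return list of class `ContingencyTable2x2` with `table` (2x2 integer
#'   matrix, rows = c(cna, background), cols = c(concordant, discordant))
#'   and the `threshold`.
#' @export
concordance_table <- function(pairs, background, cna_type = "gain",
                              threshold = 0.05) {
  if (threshold < 0 || threshold > 1) stop("threshold outside [0, 1]")
  concordant <- function(df, type) {
    f <- ifelse(is.na(df$human_frequency), 0, df$human_frequency)
    same <- df$human_cna_type == type
    f > threshold & same
  }
  sel <- pairs[pairs$cna_type == cna_type, , drop = FALSE]
  cc <- concordant(sel, cna_type)
  bc <- concordant(background, cna_type)
  tab <- matrix(c(sum(cc), sum(!cc), sum(bc), sum(!bc)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("cna", "background"),
                                c("concordant", "discordant")))
  structure(list(table = tab, threshold = threshold, cna_type = cna_type),
            class = "ContingencyTable2x2")
}

#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric two-sided p-value by the point-probability method:
#' the sum, over all tables with the observed margins, of the probabilities
#' not exceeding the observed table's probability (within relative
#' tolerance 1e-12, so exact ties are included).
#'
#' @param tbl A 2x2 integer matrix, or a `ContingencyTable2x2`.
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(tbl) {
  if (inherits(tbl, "ContingencyTable2x2")) tbl <- tbl$table
  stopifnot(all(dim(tbl) == c(2, 2)))
  if (any(tbl < 0)) stop("negative count")
  if (sum(tbl) == 0) stop("empty table")
  a <- tbl[1, 1]
  m <- tbl[1, 1] + tbl[1, 2]   # row 1 total ("white balls")
  n <- tbl[2, 1] + tbl[2, 2]   # row 2 total
  k <- tbl[1, 1] + tbl[2, 1]   # column 1 total (draws)
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-12)])
  min(1, p)
}
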