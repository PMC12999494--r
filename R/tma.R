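#' Summarize tissue-microarray ATF6 scoring counts
#'
#' Consumes a long-format count table of immunohistochemical TMA scoring —
#' ATF6-negative/positive sample counts plus grade strata of the
#' activation-high and activation-low groups — and derives the headline
#' summaries: total scored samples, the positivity percentage, and the
#' hi/low group totals summed over grade strata. The counts of the study's
#' 473-sample HCC TMA ship with the package
#' (`system.file("extdata", "tma_hcc_scores.tsv", package = "atf6scope")`).
#'
#' @param counts data.frame with columns `category` (`negative`,
#'   `positive`, `hi`, `low`), `grade`, `n` — or a path to such a TSV.
#' @return list with `n_total`, `n_positive`, `positivity_pct` (one
#'   decimal), `hi_total`, `low_total`.
#' @export
tma_summary <- function(counts) {
  if (is.character(counts)) {
    counts <- utils::read.table(counts, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
  }
  stopifnot(all(c("category", "grade", "n") %in% names(counts)))
  n_pos <- sum(counts$n[counts$category == "positive"])
  n_neg <- sum(counts$n[counts$category == "negative"])
  list(n_total = n_pos + n_neg,
       n_positive = n_pos,
       positivity_pct = round(100 * n_pos / (n_pos + n_neg), 1),
       hi_total = sum(counts$n[counts$category == "hi"]),
       low_total = sum(counts$n[counts$category == "low"]))
}
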