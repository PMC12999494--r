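#' MIBI single-cell QC thresholds
#'
#' Defaults are the study's fixed cutoffs: cell area below 71 px or above
#' 3,318 px, nuclear sum intensity below 9.21 a.u., or nuclear proportion
#' outside 0.3% to 99.8% excludes a cell; retained intensities are capped
#' at the 99.9th percentile, multiplied by 10 and arcsinh-transformed.
#' All thresholds are exposed as parameters.
#'
#' @param area_min_px,area_max_px Cell area bounds in pixels.
#' @param nuclear_sum_min_au Minimum nuclear sum intensity (a.u.).
#' @param nuclear_prop_min_pct,nuclear_prop_max_pct Nuclear proportion
#'   bounds in percent.
#' @param cap_percentile Percentile for intensity capping (0-100].
#' @param scale_factor Multiplier before the arcsinh transform.
#' @return list of class `QCThresholds`.
#' @export
qc_thresholds <- function(area_min_px = 71, area_max_px = 3318,
                          nuclear_sum_min_au = 9.21,
                          nuclear_prop_min_pct = 0.3,
                          nuclear_prop_max_pct = 99.8,
                          cap_percentile = 99.9, scale_factor = 10) {
  stopifnot(area_min_px < area_max_px,
            nuclear_prop_min_pct > 0,
            nuclear_prop_min_pct < nuclear_prop_max_pct,
            nuclear_prop_max_pct < 100,
            cap_percentile > 0, cap_percentile <= 100)
  structure(list(area_min_px = area_min_px, area_max_px = area_max_px,
                 nuclear_sum_min_au = nuclear_sum_min_au,
                 nuclear_prop_min_pct = nuclear_prop_min_pct,
                 nuclear_prop_max_pct = nuclear_prop_max_pct,
                 cap_percentile = cap_percentile,
                 scale_factor = scale_factor),
            class = "QCThresholds")
}

#' Filter single cells by the MIBI QC rules
#'
#' A cell is excluded iff its area is strictly below the minimum or strictly
#' above the maximum, its nuclear sum intensity strictly below the minimum,
#' or its nuclear proportion outside the closed keep range (bounds are
#' inclusive on the keep side: "<71" and "below 9.21" exclude strictly).
#' A cell tripping several rules is counted once per rule and once in the
#' total. The filter is idempotent.
#'
#' @param features data.frame with columns `area_px`, `nuclear_sum_au`,
#'   `nuclear_prop_pct` (plus any marker columns).
#' @param th A `QCThresholds` (default [qc_thresholds()]).
#' @return list with `retained` (filtered table), `excluded_counts` (named
#'   integer vector per rule: `area_low`, `area_high`, `nuclear_dim`,
#'   `prop_low`, `prop_high`), `n_excluded` (distinct excluded cells).
#' @export
qc_filter_cells <- function(features, th = qc_thresholds()) {
  need <- c("area_px", "nuclear_sum_au", "nuclear_prop_pct")
  missing <- setdiff(need, names(features))
  if (length(missing)) stop("missing column(s): ", paste(missing, collapse = ", "))
  rules <- list(
    area_low    = features$area_px < th$area_min_px,
    area_high   = features$area_px > th$area_max_px,
    nuclear_dim = features$nuclear_sum_au < th$nuclear_sum_min_au,
    prop_low    = features$nuclear_prop_pct < th$nuclear_prop_min_pct,
    prop_high   = features$nuclear_prop_pct > th$nuclear_prop_max_pct
  )
  excluded <- Reduce(`|`, rules)
  list(retained = features[!excluded, , drop = FALSE],
       excluded_counts = vapply(rules, sum, integer(1)),
       n_excluded = sum(excluded))
}

#' Cap, scale and arcsinh-transform marker intensities
#'
#' Per marker, values are capped at that marker's `cap_percentile`-th
#' percentile across all retained cells (type-7 quantile), multiplied by
#' `scale_factor` and arcsinh-transformed. The output is finite, monotone
#' in the input below the cap, and bounded by `asinh(scale * cap)`.
#'
#' @param intensities data.frame or matrix of per-cell marker values
#'   (retained cells only).
#' @param th A `QCThresholds` supplying `cap_percentile` and `scale_factor`.
#' @return Object of the same shape with transformed values; the per-marker
#'   caps are attached as attribute `"caps"`.
#' @export
normalize_transform <- function(intensities, th = qc_thresholds()) {
  m <- as.matrix(intensities)
  if (nrow(m) == 0L) stop("empty input")
  caps <- apply(m, 2, stats::quantile, probs = th$cap_percentile / 100,
                names = FALSE)
  out <- m
  for (j in seq_len(ncol(m))) {
    out[, j] <- asinh(pmin(m[, j], caps[[j]]) * th$scale_factor)
  }
  attr(out, "caps") <- caps
  out
}

#' Mann-Whitney U and Kolmogorov-Smirnov comparison of two samples
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test and two-sample
#' Kolmogorov-Smirnov test between two groups of values.
#'
#' @param a,b Numeric vectors (each length >= 3).
#' @return list with `n_a`, `n_b`, `mwu_u`, `mwu_p`, `ks_stat`, `ks_p`.
#' @export
compare_distributions <- function(a, b) {
  stopifnot(length(a) >= 3, length(b) >= 3)
  mwu <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
  ks <- suppressWarnings(stats::ks.test(a, b))
  list(n_a = length(a), n_b = length(b),
       mwu_u = unname(mwu$statistic), mwu_p = mwu$p.value,
       ks_stat = unname(ks$statistic), ks_p = ks$p.value)
}
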