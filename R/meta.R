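#' Hedges g standardized mean difference for one dataset
#'
#' Small-sample-corrected standardized mean difference of tumour versus
#' control values: `g = J * (mean_t - mean_c) / s_pooled` with
#' `J = 1 - 3 / (4 df - 1)`, `df = n_t + n_c - 2`, and sampling variance
#' `var_g = (n_t + n_c) / (n_t * n_c) + g^2 / (2 (n_t + n_c))`.
#'
#' @param scores_tumour,scores_control Numeric vectors (each length >= 2).
#' @param dataset Dataset identifier carried through to pooling.
#' @return A one-row data.frame of class `EffectEstimate` with columns
#'   `dataset`, `g`, `var_g`, `n_tumour`, `n_control`.
#' @export
hedges_g <- function(scores_tumour, scores_control, dataset = NA_character_) {
  nt <- length(scores_tumour); nc <- length(scores_control)
  stopifnot(nt >= 2, nc >= 2)
  df <- nt + nc - 2
  s2 <- ((nt - 1) * stats::var(scores_tumour) +
         (nc - 1) * stats::var(scores_control)) / df
  if (s2 <= 0) stop("zero pooled standard deviation")
  J <- 1 - 3 / (4 * df - 1)
  g <- J * (mean(scores_tumour) - mean(scores_control)) / sqrt(s2)
  var_g <- (nt + nc) / (nt * nc) + g^2 / (2 * (nt + nc))
  out <- data.frame(dataset = dataset, g = g, var_g = var_g,
                    n_tumour = nt, n_control = nc,
                    stringsAsFactors = FALSE)
  class(out) <- c("EffectEstimate", "data.frame")
  out
}

#' DerSimonian-Laird random-effects pooling
#'
#' Moment-based random-effects meta-analysis: with fixed-effect weights
#' `w_i = 1 / v_i`, Cochran's `Q = sum(w_i (y_i - y_FE)^2)` and
#' `tau2 = max(0, (Q - (k - 1)) / (sum(w_i) - sum(w_i^2) / sum(w_i)))`;
#' random-effects weights are `w*_i = 1 / (v_i + tau2)`, the pooled effect
#' their weighted mean, `SE = 1 / sqrt(sum(w*_i))` and the 95% CI uses the
#' normal multiplier 1.96. With a single study, `tau2 = 0` and the pooled
#' effect is that study's.
#'
#' @param effects data.frame with columns `g` (or `y`) and `var_g` (or `v`),
#'   e.g. rows from [hedges_g()].
#' @return list of class `MetaResult`: `pooled`, `se`, `ci_low`, `ci_high`,
#'   `tau2`, `Q`, `k`, `weights` (random-effects weights), `z`, `p_value`.
#' @export
dl_pool <- function(effects) {
  y <- if ("g" %in% names(effects)) effects$g else effects$y
  v <- if ("var_g" %in% names(effects)) effects$var_g else effects$v
  k <- length(y)
  stopifnot(k >= 1, length(v) == k)
  if (any(v <= 0)) stop("non-positive sampling variance")
  w <- 1 / v
  y_fe <- sum(w * y) / sum(w)
  Q <- sum(w * (y - y_fe)^2)
  tau2 <- if (k > 1) max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w))) else 0
  ws <- 1 / (v + tau2)
  pooled <- sum(ws * y) / sum(ws)
  se <- sqrt(1 / sum(ws))
  z <- pooled / se
  out <- list(pooled = pooled, se = se,
              ci_low = pooled - 1.96 * se, ci_high = pooled + 1.96 * se,
              tau2 = tau2, Q = Q, k = k, weights = ws,
              z = z, p_value = 2 * stats::pnorm(-abs(z)))
  class(out) <- "MetaResult"
  out
}

#' Forest table for a set of per-dataset effects
#'
#' Per-dataset effect, variance, random-effects weight (as percentage of
#' total) and 95% CI — the tabular content behind a forest plot.
#'
#' @param effects data.frame of stacked [hedges_g()] rows.
#' @param meta Result of [dl_pool()] on the same effects.
#' @return data.frame with one row per dataset.
#' @export
forest_table <- function(effects, meta) {
  data.frame(dataset = effects$dataset, g = effects$g, var_g = effects$var_g,
             weight_pct = 100 * meta$weights / sum(meta$weights),
             ci_low = effects$g - 1.96 * sqrt(effects$var_g),
             ci_high = effects$g + 1.96 * sqrt(effects$var_g),
             stringsAsFactors = FALSE)
}
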