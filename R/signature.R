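#' Build a paired UP/DN signature from a differential-expression table
#'
#' Statistically significant genes are selected by absolute log2 fold change
#' and BH-adjusted p-value: UP genes satisfy `log2FC >= lfc_cut` (inclusive)
#' and `p_adj < fdr_cut`; DN genes satisfy `log2FC <= -lfc_cut` and
#' `p_adj < fdr_cut`. Empty result sets are legal and reported with a
#' message.
#'
#' @param de data.frame with columns `gene`, `log2FC`, `p_adj` (unique genes,
#'   `p_adj` in \[0, 1\]).
#' @param lfc_cut Absolute log2 fold-change threshold (default 1).
#' @param fdr_cut BH-adjusted p-value threshold (default 0.05).
#' @param name Signature name.
#' @return A `SignaturePair`: list with character vectors `up`, `dn` and the
#'   `name`.
#' @export
build_signature <- function(de, lfc_cut = 1, fdr_cut = 0.05,
                            name = "signature") {
  stopifnot(is.data.frame(de), nrow(de) > 0L,
            all(c("gene", "log2FC", "p_adj") %in% names(de)))
  if (anyDuplicated(de$gene)) stop("duplicate gene ids in DE table")
  if (any(de$p_adj < 0 | de$p_adj > 1)) stop("p_adj outside [0, 1]")
  sig <- de$p_adj < fdr_cut
  up <- de$gene[sig & de$log2FC >= lfc_cut]
  dn <- de$gene[sig & de$log2FC <= -lfc_cut]
  if (length(up) == 0L) message("signature '", name, "': empty UP set")
  if (length(dn) == 0L) message("signature '", name, "': empty DN set")
  signature_pair(up, dn, name)
}

#' Construct a SignaturePair
#'
#' @param up,dn Character vectors of gene ids; must be disjoint.
#' @param name Signature name.
#' @return A `SignaturePair` list.
#' @export
signature_pair <- function(up, dn, name = "signature") {
  up <- unique(as.character(up)); dn <- unique(as.character(dn))
  if (length(intersect(up, dn))) {
    stop("UP and DN sets overlap: ",
         paste(utils::head(intersect(up, dn), 5), collapse = ", "))
  }
  structure(list(up = up, dn = dn, name = name), class = "SignaturePair")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment (via [stats::p.adjust()]): monotone
#' non-decreasing after sorting, capped at 1.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Nearest-template prediction (NTP) class calls
#'
#' Each sample is classified to the nearer of two signature-defined
#' templates: `high` is +1 on UP genes and -1 on DN genes over the signature
#' genes present in the matrix, `low` is its negation. With
#' `standardize = TRUE` (default) genes are z-scored across the cohort
#' first, so baseline expression differences between genes do not mask the
#' class contrast. Distance is 1 - Pearson correlation between the sample's
#' signature-gene expression vector and the template. Significance comes
#' from a permutation null built
#' from `n_perm` random gene sets of matched UP/DN sizes drawn from the
#' matrix genes: the p-value is the fraction of null distances at most the
#' observed distance (add-one estimator), adjusted by Benjamini-Hochberg;
#' calls with FDR below `fdr_cut` are flagged significant.
#'
#' @param expr Numeric genes-by-samples matrix.
#' @param sig A `SignaturePair`.
#' @param n_perm Number of random template permutations (default 1000; fewer
#'   than 100 draws a warning, 0 is an error).
#' @param fdr_cut FDR threshold for a significant call (default 0.05).
#' @param standardize Z-score each gene across samples before computing
#'   distances (default `TRUE`); constant genes are left at zero.
#' @return data.frame with per-sample `class` (`"high"`/`"low"`),
#'   `dist_high`, `dist_low`, `p_value`, `fdr`, `significant`.
#' @export
ntp_classify <- function(expr, sig, n_perm = 1000, fdr_cut = 0.05,
                         standardize = TRUE) {
  stopifnot(is.matrix(expr))
  if (n_perm == 0) stop("n_perm must be positive")
  if (n_perm < 100) warning("n_perm < 100: permutation p-values are coarse")
  up <- intersect(sig$up, rownames(expr))
  dn <- intersect(sig$dn, rownames(expr))
  genes <- c(up, dn)
  if (length(genes) < 2L) stop("fewer than 2 signature genes present")
  if (standardize) {
    mu <- rowMeans(expr)
    s <- apply(expr, 1, stats::sd)
    s[s == 0] <- 1
    expr <- (expr - mu) / s
  }
  template <- c(rep(1, length(up)), rep(-1, length(dn)))
  x <- expr[genes, , drop = FALSE]

  cor_dist <- function(v, tmpl) {
    if (stats::sd(v) == 0) return(1)  # uncorrelated by convention
    1 - stats::cor(v, tmpl)
  }
  d_hi <- apply(x, 2, cor_dist, tmpl = template)
  d_lo <- apply(x, 2, cor_dist, tmpl = -template)
  cls <- ifelse(d_hi <= d_lo, "high", "low")
  d_obs <- pmin(d_hi, d_lo)

  # null: distances of each sample to random templates of matched sizes
  all_genes <- rownames(expr)
  null_d <- matrix(NA_real_, n_perm, ncol(expr))
  for (b in seq_len(n_perm)) {
    g <- sample(all_genes, length(genes))
    xb <- expr[g, , drop = FALSE]
    for (j in seq_len(ncol(expr))) {
      null_d[b, j] <- cor_dist(xb[, j], template)
    }
  }
  p <- vapply(seq_len(ncol(expr)), function(j) {
    (sum(null_d[, j] <= d_obs[[j]]) + 1) / (n_perm + 1)
  }, numeric(1))
  fdr <- bh_adjust(p)
  data.frame(sample = colnames(expr), class = cls,
             dist_high = unname(d_hi), dist_low = unname(d_lo),
             p_value = p, fdr = fdr, significant = fdr < fdr_cut,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Information coefficient (IC) association with permutation test
#'
#' A signed, mutual-information-based correlation in \[-1, 1\]:
#' `IC = sign(rho) * sqrt(1 - exp(-2 I))`, where `rho` is the Pearson
#' correlation and `I` a kernel-density estimate of the mutual information
#' between `x` and `y` (bivariate Gaussian KDE on a regular grid;
#' normal-reference bandwidths, inflated against small-sample bias and
#' shrunk with increasing `|rho|`). For jointly Gaussian data
#' `I = -log(1 - rho^2) / 2`, so IC reduces to `rho`; the KDE makes it
#' sensitive to non-linear association as well. Significance is an empirical
#' permutation test shuffling `y`.
#'
#' @param x,y Numeric vectors of equal length (>= 8), finite values.
#' @param n_perm Number of permutations for the two-sided p-value
#'   (default 1000; 0 skips the test and returns `NA` p).
#' @param n_grid KDE grid resolution per axis (default 25).
#' @return list with `ic`, `p_value`, `n_perm`.
#' @export
information_coefficient <- function(x, y, n_perm = 1000, n_grid = 25) {
  stopifnot(length(x) == length(y), length(x) >= 8)
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: IC defined as 0")
    return(list(ic = 0, p_value = NA_real_, n_perm = 0L))
  }
  ic_obs <- .ic_stat(x, y, n_grid)
  p <- NA_real_
  if (n_perm > 0) {
    null_ic <- vapply(seq_len(n_perm), function(b) {
      .ic_stat(x, sample(y), n_grid)
    }, numeric(1))
    p <- (sum(abs(null_ic) >= abs(ic_obs)) + 1) / (n_perm + 1)
  }
  list(ic = ic_obs, p_value = p, n_perm = as.integer(n_perm))
}

# IC point estimate: signed sqrt(1 - exp(-2 I)) with I from a 2D Gaussian
# KDE (MASS::kde2d) integrated on the grid. Bandwidths are the normal
# reference (bandwidth.nrd) inflated by 1.5 to control the positive MI bias
# of small samples, and shrunk by (1 - 0.75 |rho|) as in the REVEALER
# lineage so that IC -> 1 for perfectly dependent data.
.ic_stat <- function(x, y, n_grid = 25) {
  rho <- stats::cor(x, y)
  bw <- c(MASS::bandwidth.nrd(x), MASS::bandwidth.nrd(y)) *
    1.5 * (1 - 0.75 * abs(rho))
  bw[bw <= 0] <- 1e-3
  pad <- 1.5
  lims <- c(range(x) + c(-pad, pad) * bw[1],
            range(y) + c(-pad, pad) * bw[2])
  kd <- MASS::kde2d(x, y, h = bw, n = n_grid, lims = lims)
  dx <- diff(kd$x[1:2]); dy <- diff(kd$y[1:2])
  z <- kd$z / (sum(kd$z) * dx * dy)      # renormalize on the grid
  px <- rowSums(z) * dy
  py <- colSums(z) * dx
  denom <- outer(px, py)
  ok <- z > 0 & denom > 0
  mi <- sum(z[ok] * log(z[ok] / denom[ok])) * dx * dy
  mi <- max(mi, 0)
  sign(rho) * sqrt(1 - exp(-2 * mi))
}
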