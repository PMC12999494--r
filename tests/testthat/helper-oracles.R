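# Independent oracles and tiny fixture builders shared across test files.
# The oracles deliberately re-derive each quantity from its definition with
# straight loops, so they share no code path with the package.

# ssGSEA running-sum score by the literal definition: walk the descending
# ranking; in-set genes accumulate (rank weight)^alpha normalized to 1,
# out-of-set genes accumulate uniform mass; sum the differences.
oracle_ssgsea_one <- function(values, gene_ids, set, alpha) {
  stopifnot(length(values) == length(gene_ids))
  ord <- order(-values, gene_ids)   # descending value, ties by id
  n <- length(values)
  in_set <- gene_ids[ord] %in% set
  w <- (n:1)^alpha
  w[!in_set] <- 0
  n_out <- sum(!in_set)
  score <- 0
  p_in <- 0; p_out <- 0
  for (i in seq_len(n)) {
    p_in <- p_in + w[i] / sum(w)
    if (n_out > 0 && !in_set[i]) p_out <- p_out + 1 / n_out
    score <- score + (p_in - p_out)
  }
  score
}

# Two-sided Fisher p by explicit enumeration of all tables with the
# observed margins, probabilities from choose() products.
oracle_fisher_two_sided <- function(tbl) {
  r1 <- sum(tbl[1, ]); r2 <- sum(tbl[2, ])
  c1 <- sum(tbl[, 1]); total <- r1 + r2
  lo <- max(0, c1 - r2); hi <- min(c1, r1)
  prob_of <- function(a) {
    choose(r1, a) * choose(r2, c1 - a) / choose(total, c1)
  }
  probs <- vapply(lo:hi, prob_of, numeric(1))
  p_obs <- prob_of(tbl[1, 1])
  sum(probs[probs <= p_obs * (1 + 1e-10)])
}

# Log-rank chi-squared statistic from the hypergeometric O-E/V definition,
# computed with explicit loops over event times.
oracle_logrank_chisq <- function(time, event, group) {
  g <- unique(group)
  stopifnot(length(g) == 2)
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g[1])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g[1])
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o_minus_e)^2 / v
}

# Brute-force compartment-to-cell assignment: for every nucleus, the cell
# it overlaps most (ties impossible for concentric discs); assignment only
# if its rounded centroid pixel lies in that cell.
oracle_assignments <- function(cells, nuclei) {
  out <- list()
  for (lab in sort(unique(nuclei[nuclei > 0]))) {
    idx <- which(nuclei == lab)
    host_labels <- cells[idx]
    host_labels <- host_labels[host_labels > 0]
    if (length(host_labels) == 0) next
    best <- as.integer(names(which.max(table(host_labels))))
    out[[as.character(lab)]] <- best
  }
  out
}

# A square label image with one centred disc object per (row, col, radius).
disc_image <- function(size, discs) {
  m <- matrix(0L, size, size)
  for (i in seq_len(nrow(discs))) {
    for (dr in -discs$r[i]:discs$r[i]) {
      for (dc in -discs$r[i]:discs$r[i]) {
        if (dr^2 + dc^2 <= discs$r[i]^2) {
          m[discs$row[i] + dr, discs$col[i] + dc] <- discs$label[i]
        }
      }
    }
  }
  as_label_image(m)
}
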