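# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's code paths (and p.adjust /
# fisher.test where they are the implementation's backend).

# Benjamini-Hochberg step-up, literal definition: q_i = min over j >= i of
# m * p_(j) / j, computed by explicit loops on the sorted p-values.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, m * ps[j] / j)
    q[i] <- min(best, 1)
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# All-pairs minimum-distance radial binning, O(n^2), explicit loops.
radial_counts_oracle <- function(cells, source_phenotype, target_phenotype,
                                 edges) {
  has <- function(ph, lab) {
    vapply(strsplit(ph, ";", fixed = TRUE),
           function(p) lab %in% trimws(p), logical(1))
  }
  src <- cells[has(cells$phenotypes, source_phenotype), , drop = FALSE]
  is_t <- has(cells$phenotypes, target_phenotype)
  is_s <- has(cells$phenotypes, source_phenotype)
  tgt <- cells[is_t & !is_s, , drop = FALSE]
  n_bins <- length(edges) - 1L
  counts <- integer(n_bins)
  for (i in seq_len(nrow(tgt))) {
    dmin <- Inf
    for (j in seq_len(nrow(src))) {
      d <- sqrt((tgt$x_um[i] - src$x_um[j])^2 +
                (tgt$y_um[i] - src$y_um[j])^2)
      if (d < dmin) dmin <- d
    }
    for (b in seq_len(n_bins)) {
      if (dmin >= edges[b] && dmin < edges[b + 1L]) {
        counts[b] <- counts[b] + 1L
        break
      }
    }
  }
  counts
}

# Two-sided Fisher exact p by enumerating the hypergeometric support and
# summing all tables with probability <= that of the observed table.
fisher_oracle <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  support <- max(0L, k - n):min(k, m)
  probs <- vapply(support, function(x) {
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k))
  }, numeric(1))
  p_obs <- probs[match(a, support)]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Full-sort oracle for DEP / payload ranking: explicit triple sort on the
# (q, |log2fc| or log2fc, id) keys via data.frame ordering.
sort_oracle <- function(q, fc, id, abs_fc = TRUE) {
  key_fc <- if (abs_fc) -abs(fc) else -fc
  id[order(q, key_fc, id, method = "radix")]
}

# Median-split oracle using the sorted-midpoint definition of the median.
dichotomize_oracle <- function(values) {
  s <- sort(values)
  n <- length(s)
  med <- if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  ifelse(values > med, "high", "low")
}

default_cfg <- function(seed = 1L, ...) sim_config(seed = seed, ...)
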