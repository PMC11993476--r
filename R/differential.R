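# Paired tumor-vs-NAT differential expression with BH FDR control.

#' Per-patient log2 fold change
#'
#' For every patient and protein, `log2((tumor + epsilon) / (nat + epsilon))`.
#' The pseudocount keeps all entries finite at zero abundance. Swapping the
#' tumor and NAT matrices negates the result (antisymmetry).
#'
#' @param mat A [paired_abundance].
#' @return A numeric matrix (patients x proteins) of log2 fold changes.
#' @examples
#' m <- paired_abundance(matrix(2, 3, 2), matrix(1, 3, 2), epsilon = 1e-9)
#' per_patient_log2fc(m)  # ~1 everywhere
#' @export
per_patient_log2fc <- function(mat) {
  stopifnot(inherits(mat, "paired_abundance"))
  log2((mat$tumor + mat$epsilon) / (mat$nat + mat$epsilon))
}

#' Paired differential test per protein
#'
#' Two-sided paired t-test on log2(abundance + epsilon) per protein, with
#' Benjamini-Hochberg step-up q-values over all tested proteins. A pair is
#' dropped protein-wise when either member is missing; proteins with fewer
#' than `min_pairs` complete pairs are flagged untested and excluded from the
#' BH family. The summary `log2fc` is the across-patient median of the
#' per-patient log2 fold change (robust, and faithful to a per-patient
#' reading of tumor specificity).
#'
#' The t-statistics are computed column-wise in closed form (mean difference
#' over its standard error), which is algebraically identical to
#' `t.test(paired = TRUE)` but vectorised across proteins. A protein whose
#' paired differences are identically zero gets statistic 0 and p = 1.
#'
#' @param mat A [paired_abundance].
#' @param min_pairs Minimum complete pairs for a protein to be tested.
#' @return A `data.frame` of class `diff_expression_table` with columns
#'   `protein_id`, `log2fc`, `p_value`, `q_value`, `rank`, `n_pairs`,
#'   `tested`. Ranks (q ascending, ties by |log2fc| descending then id) are
#'   a permutation of 1..m over tested proteins; untested proteins carry NA.
#' @export
paired_differential_test <- function(mat, min_pairs = 3L) {
  stopifnot(inherits(mat, "paired_abundance"))
  lt <- log2(mat$tumor + mat$epsilon)
  ln <- log2(mat$nat + mat$epsilon)
  d <- lt - ln
  ok <- is.finite(d)
  n_pairs <- colSums(ok)
  tested <- n_pairs >= min_pairs
  if (!any(tested))
    stop("no testable proteins: every protein has fewer than ", min_pairs,
         " complete pairs", call. = FALSE)

  m <- ncol(d)
  mean_d <- colMeans(d, na.rm = TRUE)
  ss <- colSums(d^2, na.rm = TRUE) - n_pairs * mean_d^2
  sd_d <- sqrt(pmax(ss, 0) / pmax(n_pairs - 1L, 1L))
  se <- sd_d / sqrt(n_pairs)

  tstat <- rep(NA_real_, m)
  pval <- rep(NA_real_, m)
  nz <- tested & se > 0
  tstat[nz] <- mean_d[nz] / se[nz]
  pval[nz] <- 2 * stats::pt(abs(tstat[nz]), df = n_pairs[nz] - 1L,
                            lower.tail = FALSE)
  degen <- tested & se == 0
  tstat[degen] <- ifelse(mean_d[degen] == 0, 0, sign(mean_d[degen]) * Inf)
  pval[degen] <- ifelse(mean_d[degen] == 0, 1, 0)

  qval <- rep(NA_real_, m)
  qval[tested] <- stats::p.adjust(pval[tested], method = "BH")

  fc <- per_patient_log2fc(mat)
  l2fc <- apply(fc, 2L, stats::median, na.rm = TRUE)

  tab <- data.frame(
    protein_id = mat$protein_ids,
    log2fc = unname(l2fc),
    p_value = pval,
    q_value = qval,
    rank = NA_integer_,
    n_pairs = unname(n_pairs),
    tested = unname(tested),
    stringsAsFactors = FALSE
  )
  ord <- dep_order(tab$q_value[tested], tab$log2fc[tested],
                   tab$protein_id[tested])
  tab$rank[tested][ord] <- seq_len(sum(tested))
  class(tab) <- c("diff_expression_table", "data.frame")
  tab
}

# Canonical DEP ordering: q ascending, ties broken by |log2fc| descending,
# then protein id lexicographic. Returns an ordering permutation.
dep_order <- function(q, log2fc, id) {
  order(q, -abs(log2fc), id, method = "radix")
}

#' Top-k differentially expressed proteins
#'
#' Sorts tested proteins by q-value ascending (ties: |log2fc| descending,
#' then identifier) after filtering to the requested direction of change,
#' and returns the first `k` identifiers.
#'
#' @param table A `diff_expression_table` from [paired_differential_test()].
#' @param k Number of proteins to return (>= 1).
#' @param direction `"up"` (log2fc > 0), `"down"` (log2fc < 0), or `"both"`.
#' @return Character vector of protein identifiers, best first. If fewer
#'   than `k` qualify, all are returned with a warning.
#' @export
top_k_deps <- function(table, k, direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  if (!is.numeric(k) || length(k) != 1L || k < 1)
    stop("k must be a single integer >= 1", call. = FALSE)
  tab <- table[table$tested, , drop = FALSE]
  tab <- switch(direction,
    up = tab[tab$log2fc > 0, , drop = FALSE],
    down = tab[tab$log2fc < 0, , drop = FALSE],
    both = tab
  )
  ord <- dep_order(tab$q_value, tab$log2fc, tab$protein_id)
  ids <- tab$protein_id[ord]
  if (length(ids) < k) {
    warning("only ", length(ids), " proteins available for k = ", k,
            call. = FALSE)
    return(ids)
  }
  ids[seq_len(k)]
}

#' Write a differential expression table as TSV
#'
#' @param table A `diff_expression_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_diff_table <- function(table, path) {
  utils::write.table(
    table[, c("protein_id", "log2fc", "p_value", "q_value", "rank",
              "n_pairs")],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
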