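# Associations between target expression and externally computed immune
# cell fractions / scores: median split group tests + correlations.

#' Validate an immune fraction / score table
#'
#' Fraction columns (names not ending in `_score` / `score`) must lie in
#' `[0, 1]`; score columns are unbounded. Sample ids (rownames) must be
#' unique. Deconvolution itself is consumed, never computed here.
#'
#' @param table `data.frame`, samples in rows, cell types / scores in
#'   columns; rownames are sample ids.
#' @param provenance Label of the producing tool (e.g. "CIBERSORT").
#' @return The validated table with a `provenance` attribute.
#' @export
fraction_table <- function(table, provenance = "unknown") {
  if (!is.data.frame(table) || is.null(rownames(table)))
    stop("fraction table must be a data.frame with sample-id rownames",
         call. = FALSE)
  if (anyDuplicated(rownames(table)))
    stop("sample ids must be unique", call. = FALSE)
  is_score <- grepl("score$", names(table), ignore.case = TRUE)
  for (j in which(!is_score)) {
    v <- table[[j]]
    if (any(v < 0 | v > 1, na.rm = TRUE))
      stop("fraction column '", names(table)[j],
           "' has values outside [0, 1]", call. = FALSE)
  }
  attr(table, "provenance") <- provenance
  table
}

#' Associate target expression with immune fractions and scores
#'
#' For every column of the fraction table: (i) a median-split group test --
#' samples are dichotomized on expression with the same rule as the spatial
#' module ([dichotomize_samples()]) and the column compared between groups
#' ([compare_groups()]); (ii) Pearson and Spearman correlations between
#' expression and the column. Two-sided tests, raw p-values (BH adjustment
#' available via `adjust`).
#'
#' @param expr Named numeric vector of per-sample expression.
#' @param table A fraction table (see [fraction_table()]); rownames are
#'   sample ids. Only samples present in both are used (>= 4 required).
#' @param methods Subset of `c("median_split", "pearson", "spearman")`.
#' @param group_test `"t"` or `"mann_whitney"` for the median-split test.
#' @param adjust Apply BH adjustment across results (default FALSE; raw
#'   p-values are reported as-is).
#' @return `data.frame` with one row per (variable, method): `variable`,
#'   `method`, `statistic`, `p_value`, `effect` (mean difference or
#'   correlation r), `flag` (e.g. `"constant"` when a correlation is
#'   undefined).
#' @export
associate_expression_with_fractions <- function(
    expr, table,
    methods = c("median_split", "pearson", "spearman"),
    group_test = c("t", "mann_whitney"),
    adjust = FALSE) {
  methods <- match.arg(methods, several.ok = TRUE)
  group_test <- match.arg(group_test)
  shared <- intersect(names(expr), rownames(table))
  if (length(shared) < 4L)
    stop("fewer than 4 samples shared between expression and table",
         call. = FALSE)
  e <- expr[shared]
  tab <- table[shared, , drop = FALSE]
  grp <- dichotomize_samples(e)

  rows <- list()
  for (v in names(tab)) {
    y <- tab[[v]]
    constant <- stats::sd(y) == 0
    if ("median_split" %in% methods) {
      cmp <- compare_groups(y[grp == "high"], y[grp == "low"],
                            method = group_test)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, method = paste0("median_split_", group_test),
        statistic = cmp$statistic, p_value = cmp$p_value,
        effect = cmp$mean_difference,
        flag = if (cmp$degenerate) "degenerate" else "",
        stringsAsFactors = FALSE)
    }
    for (cm in intersect(methods, c("pearson", "spearman"))) {
      if (constant) {
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, method = cm, statistic = NA_real_,
          p_value = NA_real_, effect = NA_real_, flag = "constant",
          stringsAsFactors = FALSE)
      } else {
        ct <- suppressWarnings(stats::cor.test(e, y, method = cm))
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, method = cm, statistic = unname(ct$statistic),
          p_value = ct$p.value, effect = unname(ct$estimate), flag = "",
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (adjust) out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Read a fraction table TSV
#'
#' First column `sample_id`, remaining columns cell-type fractions or
#' scores.
#'
#' @param path TSV path.
#' @param provenance Producing-tool label.
#' @return A validated fraction table.
#' @export
read_fraction_table <- function(path, provenance = "unknown") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  rownames(df) <- df[[1L]]
  fraction_table(df[, -1L, drop = FALSE], provenance = provenance)
}
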