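# Radial-distance proximity statistics on multiplexed-immunofluorescence
# cell maps, and median-split group comparisons.

#' mIF cell map
#'
#' Per-cell coordinates (um) and phenotype labels for one sample. A cell can
#' carry several phenotypes; the on-disk form joins them with semicolons
#' (e.g. `"CD66c+;PD-L1+"`).
#'
#' @param cells `data.frame` with columns `sample_id`, `x_um`, `y_um`,
#'   `phenotypes` (semicolon-joined labels).
#' @return An object of class `cell_map`.
#' @export
cell_map <- function(cells) {
  need <- c("sample_id", "x_um", "y_um", "phenotypes")
  if (!is.data.frame(cells) || !all(need %in% names(cells)))
    stop("cells must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (any(!is.finite(cells$x_um)) || any(!is.finite(cells$y_um)))
    stop("cell coordinates must be finite", call. = FALSE)
  structure(list(cells = cells), class = "cell_map")
}

#' @export
print.cell_map <- function(x, ...) {
  cat("cell_map:", nrow(x$cells), "cells, sample(s):",
      paste(unique(x$cells$sample_id), collapse = ", "), "\n")
  invisible(x)
}

#' Read / write a cell table CSV
#'
#' Columns `sample_id,x_um,y_um,phenotypes` with semicolon-joined phenotype
#' labels.
#'
#' @param path CSV path.
#' @return A [cell_map]; writer returns `path` invisibly.
#' @export
read_cell_table <- function(path) {
  cell_map(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_cell_table
#' @param map A [cell_map] to write.
#' @export
write_cell_table <- function(map, path) {
  utils::write.csv(map$cells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

has_phenotype <- function(phenotypes, label) {
  vapply(strsplit(phenotypes, ";", fixed = TRUE),
         function(p) label %in% trimws(p), logical(1))
}

#' Proportion of cells carrying a phenotype
#'
#' @param map A [cell_map] with at least one cell.
#' @param phenotype Phenotype label, e.g. `"CD138+"`.
#' @return Fraction in `[0, 1]`.
#' @export
phenotype_proportion <- function(map, phenotype) {
  stopifnot(inherits(map, "cell_map"))
  if (nrow(map$cells) == 0)
    stop("cell map is empty", call. = FALSE)
  mean(has_phenotype(map$cells$phenotypes, phenotype))
}

#' Radial bin specification
#'
#' Strictly increasing, non-negative distance edges (um) defining half-open
#' bins `[lo, hi)`. The default `(0, 50, 100, 150, 200)` yields the bands
#' 0-50, 50-100, 100-150, 150-200 um; a cell at exactly 50 um falls in the
#' 50-100 band.
#'
#' @param edges Numeric edges.
#' @return A validated numeric vector of class `radial_bins`.
#' @export
radial_bins <- function(edges = c(0, 50, 100, 150, 200)) {
  if (any(edges < 0) || any(diff(edges) <= 0))
    stop("bin edges must be non-negative and strictly increasing",
         call. = FALSE)
  structure(as.numeric(edges), class = "radial_bins")
}

#' Target-cell counts by distance band from the nearest source cell
#'
#' Each target-phenotype cell is assigned to the half-open band containing
#' its minimum Euclidean distance to any source-phenotype cell; each target
#' is counted once (nearest-source convention, no multi-counting). Cells
#' carrying both phenotypes are excluded from the targets; targets beyond
#' the last edge are uncounted. No edge correction is applied (raw counts).
#'
#' @param map A [cell_map].
#' @param source_phenotype,target_phenotype Phenotype labels.
#' @param bins A [radial_bins] (or numeric edges).
#' @return Named integer vector of per-band counts, with attributes
#'   `n_beyond` (targets past the last edge), `n_excluded` (co-labeled
#'   cells), `n_targets` (total target cells incl. exclusions), and
#'   `per_source` (counts divided by the number of source cells).
#'   Conservation: `sum(counts) + n_beyond + n_excluded == n_targets`.
#' @export
radial_bin_counts <- function(map, source_phenotype, target_phenotype,
                              bins = radial_bins()) {
  stopifnot(inherits(map, "cell_map"))
  edges <- as.numeric(bins)
  cells <- map$cells
  is_src <- has_phenotype(cells$phenotypes, source_phenotype)
  is_tgt <- has_phenotype(cells$phenotypes, target_phenotype)
  if (!any(is_src))
    stop("no source cells with phenotype '", source_phenotype,
         "': radial counts are undefined", call. = FALSE)
  co <- is_src & is_tgt
  tgt <- is_tgt & !co
  n_bins <- length(edges) - 1L
  labels <- paste0(utils::head(edges, -1L), "-", edges[-1L])
  counts <- stats::setNames(integer(n_bins), labels)
  n_beyond <- 0L
  if (any(tgt)) {
    d <- nearest_distance(cells$x_um[tgt], cells$y_um[tgt],
                          cells$x_um[is_src], cells$y_um[is_src])
    # findInterval gives i with edges[i] <= d < edges[i+1]: half-open bands
    bin <- findInterval(d, edges)
    inside <- bin >= 1L & bin <= n_bins
    tab <- tabulate(bin[inside], nbins = n_bins)
    counts[] <- tab
    n_beyond <- sum(!inside)
  }
  attr(counts, "n_beyond") <- n_beyond
  attr(counts, "n_excluded") <- sum(co)
  attr(counts, "n_targets") <- sum(is_tgt)
  attr(counts, "per_source") <- counts / sum(is_src)
  counts
}

#' Median-split dichotomization of samples
#'
#' Samples with value strictly above the median are labeled `"high"`, the
#' rest `"low"` (a value equal to the median goes to `"low"`). If all
#' values are identical every sample is `"low"`, with a warning.
#'
#' @param values Named (or plain) numeric vector, one value per sample.
#' @return Character vector of `"high"` / `"low"` labels, names preserved.
#' @export
dichotomize_samples <- function(values) {
  if (length(values) < 2L)
    stop("at least 2 samples are required", call. = FALSE)
  med <- stats::median(values)
  if (all(values == values[1L]))
    warning("all values identical: every sample labeled 'low'",
            call. = FALSE)
  labels <- ifelse(values > med, "high", "low")
  stats::setNames(labels, names(values))
}

#' Two-group comparison of a per-sample statistic
#'
#' Two-sided comparison of the high and low groups with group means
#' reported. `"t"` uses Welch's t-test; `"mann_whitney"` the Wilcoxon
#' rank-sum test. When both groups are constant the t-test is undefined;
#' the mean difference is still reported with `p_value = NA` and a
#' `degenerate` flag.
#'
#' @param high,low Numeric vectors (each length >= 2).
#' @param method `"t"` or `"mann_whitney"`.
#' @return List: `statistic`, `p_value`, `mean_high`, `mean_low`,
#'   `mean_difference`, `method`, `degenerate`.
#' @export
compare_groups <- function(high, low, method = c("t", "mann_whitney")) {
  method <- match.arg(method)
  if (length(high) < 2L || length(low) < 2L)
    stop("each group needs at least 2 observations", call. = FALSE)
  means <- c(mean(high), mean(low))
  if (method == "t") {
    res <- tryCatch(stats::t.test(high, low), error = function(e) NULL)
    if (is.null(res))
      return(list(statistic = NA_real_, p_value = NA_real_,
                  mean_high = means[1L], mean_low = means[2L],
                  mean_difference = means[1L] - means[2L],
                  method = method, degenerate = TRUE))
    stat <- unname(res$statistic); p <- res$p.value
  } else {
    res <- suppressWarnings(stats::wilcox.test(high, low))
    stat <- unname(res$statistic); p <- res$p.value
  }
  list(statistic = stat, p_value = p,
       mean_high = means[1L], mean_low = means[2L],
       mean_difference = means[1L] - means[2L],
       method = method, degenerate = FALSE)
}
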