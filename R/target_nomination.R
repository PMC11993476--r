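# Funnel DEPs to ADC target candidates: surfaceome membrane filter,
# ordinal normal-tissue expression index, per-patient specificity ranking.

#' Surfaceome (membrane-protein) catalog
#'
#' A set of cell-surface protein symbols, optionally with an alias map
#' resolving alternative symbols to the canonical catalog entry. All
#' matching downstream is case-insensitive.
#'
#' @param membrane_ids Character vector of membrane protein symbols.
#' @param alias_map Optional named character vector, `alias -> canonical`.
#' @return An object of class `surfaceome_catalog`.
#' @export
surfaceome_catalog <- function(membrane_ids, alias_map = NULL) {
  ids <- unique(toupper(membrane_ids))
  if (!is.null(alias_map)) {
    if (is.null(names(alias_map)))
      stop("alias_map must be named (alias -> canonical)", call. = FALSE)
    alias_map <- stats::setNames(toupper(alias_map),
                                 toupper(names(alias_map)))
    if (anyDuplicated(names(alias_map)))
      stop("alias_map aliases must be unique", call. = FALSE)
  }
  structure(list(membrane_ids = ids, alias_map = alias_map),
            class = "surfaceome_catalog")
}

#' @export
print.surfaceome_catalog <- function(x, ...) {
  cat("surfaceome_catalog:", length(x$membrane_ids), "membrane proteins,",
      length(x$alias_map), "aliases\n")
  invisible(x)
}

#' Read / write a surfaceome catalog (one symbol per line)
#'
#' @param path File path.
#' @param alias_map Optional alias map passed to [surfaceome_catalog()].
#' @return A [surfaceome_catalog]; the writer returns `path` invisibly.
#' @export
read_surfaceome <- function(path, alias_map = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  surfaceome_catalog(lines[nzchar(lines)], alias_map = alias_map)
}

#' @rdname read_surfaceome
#' @param catalog A [surfaceome_catalog] to write.
#' @export
write_surfaceome <- function(catalog, path) {
  writeLines(catalog$membrane_ids, path)
  invisible(path)
}

resolve_symbol <- function(ids, catalog) {
  up <- toupper(ids)
  if (!is.null(catalog$alias_map)) {
    hit <- match(up, names(catalog$alias_map))
    up[!is.na(hit)] <- catalog$alias_map[hit[!is.na(hit)]]
  }
  up
}

#' Filter proteins to the cell-surface proteome
#'
#' Order-preserving subset of `dep_ids` present in the catalog after
#' case-insensitive alias resolution. Antibody-based therapeutics can only
#' engage antigens displayed on the cell membrane, so this is the first
#' funnel stage after differential ranking.
#'
#' @param dep_ids Candidate protein identifiers, best first.
#' @param catalog A [surfaceome_catalog].
#' @return The retained identifiers (original spelling, original order);
#'   possibly empty.
#' @export
membrane_filter <- function(dep_ids, catalog) {
  stopifnot(inherits(catalog, "surfaceome_catalog"))
  dep_ids[resolve_symbol(dep_ids, catalog) %in% catalog$membrane_ids]
}

# ---------------------------------------------------------------------------
# Ordinal normal-tissue expression table

.level_scores <- c(not_detected = 0L, low = 1L, medium = 2L, high = 3L)

#' Parse ordinal tissue-expression levels
#'
#' Accepts HPA-style level strings case-insensitively (`"not detected"`,
#' `"not_detected"`, `"nd"`, `"low"`, `"medium"`, `"high"`) or the integer
#' scores 0-3. Unknown strings raise an error rather than silently scoring
#' 0, which would deflate the index.
#'
#' @param x Character (or integer 0-3) vector of levels.
#' @return Integer scores in 0..3.
#' @export
parse_expression_level <- function(x) {
  if (is.numeric(x)) {
    if (any(!x %in% 0:3)) stop("numeric levels must be in 0..3", call. = FALSE)
    return(as.integer(x))
  }
  key <- gsub("[ -]", "_", tolower(trimws(x)))
  key[key == "nd"] <- "not_detected"
  score <- .level_scores[key]
  if (anyNA(score))
    stop("unknown expression level(s): ",
         paste(unique(x[is.na(score)]), collapse = ", "), call. = FALSE)
  as.integer(score)
}

#' Ordinal normal-tissue expression table
#'
#' Protein x tissue matrix of ordinal expression levels scored
#' `not_detected = 0 < low = 1 < medium = 2 < high = 3`, emulating
#' Human-Protein-Atlas-style normal tissue annotation (default 41 tissues).
#'
#' @param levels Matrix (proteins x tissues) of integer scores 0-3 or level
#'   strings; rownames are protein ids, colnames tissue names.
#' @return An object of class `tissue_expression_table`.
#' @export
tissue_expression_table <- function(levels) {
  if (is.character(levels)) {
    dm <- dim(levels); dn <- dimnames(levels)
    levels <- matrix(parse_expression_level(levels), dm[1L], dm[2L],
                     dimnames = dn)
  }
  if (!is.matrix(levels) || is.null(rownames(levels)))
    stop("levels must be a matrix with protein rownames", call. = FALSE)
  storage.mode(levels) <- "integer"
  if (any(!levels %in% 0:3))
    stop("levels must be scores in 0..3", call. = FALSE)
  structure(list(levels = levels, protein_ids = rownames(levels),
                 tissue_names = colnames(levels)),
            class = "tissue_expression_table")
}

#' @export
print.tissue_expression_table <- function(x, ...) {
  cat("tissue_expression_table:", length(x$protein_ids), "proteins x",
      length(x$tissue_names), "tissues\n")
  invisible(x)
}

#' Read / write a tissue expression table (TSV, string levels)
#'
#' TSV layout: first column `protein_id`, remaining columns one per tissue,
#' cells holding level strings. Round-trips losslessly.
#'
#' @param path File path.
#' @return A [tissue_expression_table]; writer returns `path` invisibly.
#' @export
read_tissue_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  tissue_expression_table(m)
}

#' @rdname read_tissue_table
#' @param table A [tissue_expression_table] to write.
#' @export
write_tissue_table <- function(table, path) {
  lab <- names(.level_scores)
  chr <- matrix(lab[table$levels + 1L], nrow(table$levels),
                dimnames = dimnames(table$levels))
  df <- data.frame(protein_id = rownames(chr), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Normal-tissue expression index
#'
#' Sum over tissues of the ordinal expression score (high = 3, medium = 2,
#' low = 1, not detected = 0). Lower index means more tumor-restricted
#' expression, hence a safer ADC target. Range 0 to 3 x n_tissues
#' (0-123 for the default 41 tissues).
#'
#' @param table A [tissue_expression_table].
#' @param protein_id Protein to score; must be present in the table.
#' @return Integer index.
#' @examples
#' tab <- tissue_expression_table(
#'   matrix(3L, 1, 41, dimnames = list("P1", NULL)))
#' normal_tissue_index(tab, "P1")  # 123
#' @export
normal_tissue_index <- function(table, protein_id) {
  stopifnot(inherits(table, "tissue_expression_table"))
  if (!protein_id %in% table$protein_ids)
    stop("unknown protein id: ", protein_id, call. = FALSE)
  sum(table$levels[protein_id, ])
}

# ---------------------------------------------------------------------------
# Specificity profiling and nomination

#' Per-patient tumor-specificity profile of a candidate
#'
#' From the patients x proteins matrix of per-patient log2 fold changes,
#' summarises a candidate as (i) its median log2FC across patients and
#' (ii) for each reference target, the fraction of patients in which the
#' candidate's log2FC strictly exceeds the reference's (ties do not credit
#' the candidate).
#'
#' @param fc_matrix Patients x proteins log2FC matrix (see
#'   [per_patient_log2fc()]).
#' @param candidate Candidate protein id (a column of `fc_matrix`).
#' @param references Character vector of reference protein ids (for
#'   instance established ADC targets such as HER2, TROP2, CLDN18).
#' @return List with `specificity_median` and `win_fraction_vs_refs`
#'   (named numeric in `[0, 1]`).
#' @export
specificity_profile <- function(fc_matrix, candidate,
                                references = character(0)) {
  missing <- setdiff(c(candidate, references), colnames(fc_matrix))
  if (length(missing) > 0)
    stop("protein(s) absent from fc_matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  cand <- fc_matrix[, candidate]
  wins <- vapply(references,
                 function(r) mean(cand > fc_matrix[, r]),
                 numeric(1))
  list(specificity_median = stats::median(cand),
       win_fraction_vs_refs = wins)
}

#' Nominate ADC target candidates
#'
#' Runs the nomination funnel: take the top-k upregulated DEPs, keep the
#' membrane-localized subset, score each by its normal-tissue expression
#' index, and rank candidates by index ascending (ties: specificity median
#' descending, then identifier). All component scores are retained.
#'
#' @param diff A `diff_expression_table`.
#' @param catalog A [surfaceome_catalog].
#' @param tissue_table A [tissue_expression_table] covering the candidates.
#' @param fc_matrix Patients x proteins log2FC matrix.
#' @param k Number of top DEPs entering the funnel (default 20).
#' @param references Optional established-target ids for win fractions.
#' @return A `data.frame` of class `nomination_report` with one row per
#'   candidate: `protein_id`, `rank`, `q_value`, `log2fc`, `nt_index`,
#'   `specificity_median`, plus `win_frac_<ref>` columns when references
#'   are given. Empty (with a warning) when no DEP is membrane-localized.
#' @export
nominate_targets <- function(diff, catalog, tissue_table, fc_matrix,
                             k = 20L, references = character(0)) {
  top <- suppressWarnings(top_k_deps(diff, k, direction = "up"))
  memb <- membrane_filter(top, catalog)
  if (length(memb) == 0) {
    warning("no membrane-localized protein among the top-", k, " DEPs",
            call. = FALSE)
    rep <- data.frame(protein_id = character(0), rank = integer(0),
                      q_value = numeric(0), log2fc = numeric(0),
                      nt_index = integer(0),
                      specificity_median = numeric(0),
                      stringsAsFactors = FALSE)
    class(rep) <- c("nomination_report", "data.frame")
    return(rep)
  }
  nt <- vapply(memb, function(p) normal_tissue_index(tissue_table, p),
               integer(1))
  prof <- lapply(memb, function(p)
    specificity_profile(fc_matrix, p, references))
  spec_med <- vapply(prof, `[[`, numeric(1), "specificity_median")
  idx <- match(memb, diff$protein_id)
  rep <- data.frame(
    protein_id = memb,
    rank = NA_integer_,
    q_value = diff$q_value[idx],
    log2fc = diff$log2fc[idx],
    nt_index = unname(nt),
    specificity_median = spec_med,
    stringsAsFactors = FALSE
  )
  if (length(references) > 0) {
    wf <- do.call(rbind, lapply(prof, `[[`, "win_fraction_vs_refs"))
    colnames(wf) <- paste0("win_frac_", references)
    rep <- cbind(rep, wf)
  }
  ord <- order(rep$nt_index, -rep$specificity_median, rep$protein_id,
               method = "radix")
  rep <- rep[ord, , drop = FALSE]
  rep$rank <- seq_len(nrow(rep))
  rownames(rep) <- NULL
  class(rep) <- c("nomination_report", "data.frame")
  rep
}

#' @export
print.nomination_report <- function(x, ...) {
  cat("nomination_report:", nrow(x), "candidate target(s)\n")
  if (nrow(x) > 0) print.data.frame(utils::head(x, 10L))
  invisible(x)
}
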