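# Druggable-DEP screen: intersect upregulated DEPs with drug-target
# catalogs and rank by FDR.

validate_drug_catalog <- function(catalog) {
  need <- c("target_id", "drug_name", "phase", "source_db")
  if (!is.data.frame(catalog) || !all(need %in% names(catalog)))
    stop("drug catalog must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(catalog$phase),
                 c("approved", "clinical_trial", "preclinical"))
  if (length(bad) > 0)
    stop("unknown development phase(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  key <- paste(catalog$target_id, catalog$drug_name, catalog$source_db,
               sep = "\r")
  if (anyDuplicated(key))
    stop("(target, drug, source) triples must be unique", call. = FALSE)
  catalog
}

#' Read / write a drug-target catalog (CSV)
#'
#' Columns: `target_id`, `drug_name`, `phase`
#' (approved / clinical_trial / preclinical), `source_db`.
#'
#' @param path File path.
#' @return A validated catalog `data.frame`; writer returns `path`
#'   invisibly.
#' @export
read_drug_catalog <- function(path) {
  validate_drug_catalog(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_drug_catalog
#' @param catalog Catalog `data.frame` to write.
#' @export
write_drug_catalog <- function(catalog, path) {
  utils::write.csv(validate_drug_catalog(catalog), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Druggable differentially expressed proteins
#'
#' Intersects DEPs passing the FDR threshold (and direction filter) with
#' catalog targets that have at least one approved or clinical-trial drug.
#' Preclinical-only targets are excluded: the screen looks for payloads with
#' established human pharmacology. Duplicate drug records across source
#' databases are collapsed at reporting, with provenance retained.
#'
#' @param diff A `diff_expression_table`.
#' @param catalog Drug-target catalog `data.frame`
#'   (see [read_drug_catalog()]).
#' @param q_threshold FDR threshold in (0, 1], default 0.05.
#' @param direction `"up"` (log2fc > 0, the default) or `"both"`.
#' @return A `data.frame` of class `payload_nominations`: one row per
#'   (target, drug) pair with `target_id`, `q_value`, `log2fc`,
#'   `drug_name`, `phase`, `source_db`. Attributes `n_targets` and
#'   `n_pairs` give both countings.
#' @export
druggable_deps <- function(diff, catalog, q_threshold = 0.05,
                           direction = c("up", "both")) {
  direction <- match.arg(direction)
  if (!is.numeric(q_threshold) || q_threshold <= 0 || q_threshold > 1)
    stop("q_threshold must lie in (0, 1]", call. = FALSE)
  validate_drug_catalog(catalog)
  if (nrow(catalog) == 0)
    warning("empty drug catalog: no payloads can be nominated",
            call. = FALSE)

  deps <- diff[diff$tested & !is.na(diff$q_value) &
                 diff$q_value < q_threshold, , drop = FALSE]
  if (direction == "up")
    deps <- deps[deps$log2fc > 0, , drop = FALSE]

  qual <- catalog[catalog$phase %in% c("approved", "clinical_trial"), ,
                  drop = FALSE]
  hit <- merge(deps[, c("protein_id", "q_value", "log2fc")],
               qual, by.x = "protein_id", by.y = "target_id")
  # collapse duplicate (target, drug) records across source databases
  key <- paste(hit$protein_id, hit$drug_name, sep = "\r")
  prov <- tapply(hit$source_db, key, function(s)
    paste(sort(unique(s)), collapse = ";"))
  hit <- hit[!duplicated(key), , drop = FALSE]
  hit$source_db <- unname(prov[paste(hit$protein_id, hit$drug_name,
                                     sep = "\r")])
  names(hit)[names(hit) == "protein_id"] <- "target_id"
  hit <- hit[order(hit$target_id, hit$drug_name), , drop = FALSE]
  rownames(hit) <- NULL
  attr(hit, "n_targets") <- length(unique(hit$target_id))
  attr(hit, "n_pairs") <- nrow(hit)
  class(hit) <- c("payload_nominations", "data.frame")
  hit
}

#' Rank payload-target nominations by FDR
#'
#' Collapses nominations to one row per target, sorted by q-value ascending
#' (ties: log2fc descending, then identifier), assigns ranks 1..k and keeps
#' the top k. Each retained target lists its qualifying drugs.
#'
#' @param noms A `payload_nominations` object from [druggable_deps()].
#' @param k Number of targets to keep (default 10).
#' @return A `data.frame` with `target_id`, `q_value`, `log2fc`, `rank`,
#'   and a semicolon-joined `drugs` column.
#' @export
rank_payload_targets <- function(noms, k = 10L) {
  if (!is.numeric(k) || length(k) != 1L || k < 1)
    stop("k must be a single integer >= 1", call. = FALSE)
  if (nrow(noms) == 0)
    return(data.frame(target_id = character(0), q_value = numeric(0),
                      log2fc = numeric(0), rank = integer(0),
                      drugs = character(0), stringsAsFactors = FALSE))
  per <- noms[!duplicated(noms$target_id), c("target_id", "q_value",
                                             "log2fc"), drop = FALSE]
  drugs <- tapply(paste0(noms$drug_name, " (", noms$phase, ")"),
                  noms$target_id, paste, collapse = "; ")
  per$drugs <- unname(drugs[per$target_id])
  ord <- order(per$q_value, -per$log2fc, per$target_id, method = "radix")
  per <- per[ord, , drop = FALSE]
  per <- utils::head(per, k)
  per$rank <- seq_len(nrow(per))
  rownames(per) <- NULL
  per[, c("target_id", "q_value", "log2fc", "rank", "drugs")]
}
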