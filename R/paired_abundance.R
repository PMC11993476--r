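#' Paired tumor/NAT protein abundance matrix
#'
#' Container for linear-scale protein abundances measured in tumor tissue and
#' normal adjacent tissue (NAT) of the same patients. Row i of `tumor` and
#' `nat` refer to the same patient, so per-patient ratios are meaningful.
#'
#' @param tumor,nat Numeric matrices (patients x proteins), linear scale,
#'   no negative values. `NA` marks a missing measurement.
#' @param patient_ids,protein_ids Identifiers; default to dimnames.
#' @param epsilon Pseudocount added before log transformation (linear
#'   scale). Guards zeros without distorting large intensities.
#'
#' @return An object of class `paired_abundance`.
#' @export
paired_abundance <- function(tumor, nat,
                             patient_ids = rownames(tumor),
                             protein_ids = colnames(tumor),
                             epsilon = 1) {
  if (!is.matrix(tumor) || !is.matrix(nat))
    stop("tumor and nat must be matrices", call. = FALSE)
  if (!all(dim(tumor) == dim(nat)))
    stop("tumor and nat matrices must have identical shape", call. = FALSE)
  if (any(tumor < 0, na.rm = TRUE) || any(nat < 0, na.rm = TRUE))
    stop("abundances must be non-negative", call. = FALSE)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
    stop("epsilon must be a single positive number", call. = FALSE)
  if (is.null(patient_ids)) patient_ids <- paste0("PT", seq_len(nrow(tumor)))
  if (is.null(protein_ids)) protein_ids <- paste0("PROT", seq_len(ncol(tumor)))
  dimnames(tumor) <- dimnames(nat) <- list(patient_ids, protein_ids)
  structure(
    list(tumor = tumor, nat = nat, patient_ids = patient_ids,
         protein_ids = protein_ids, epsilon = epsilon),
    class = "paired_abundance"
  )
}

#' @export
print.paired_abundance <- function(x, ...) {
  cat("paired_abundance:", length(x$patient_ids), "patients x",
      length(x$protein_ids), "proteins (epsilon =", x$epsilon, ")\n")
  invisible(x)
}

#' Write / read a paired abundance matrix as TSV
#'
#' The on-disk form is a single long-format TSV with columns
#' `patient_id`, `protein_id`, `tumor`, `nat`, which round-trips losslessly.
#'
#' @param mat A [paired_abundance] object.
#' @param path Output file path.
#' @return `write_paired_abundance` returns `path` invisibly;
#'   `read_paired_abundance` returns a [paired_abundance].
#' @export
write_paired_abundance <- function(mat, path) {
  stopifnot(inherits(mat, "paired_abundance"))
  long <- data.frame(
    patient_id = rep(mat$patient_ids, times = length(mat$protein_ids)),
    protein_id = rep(mat$protein_ids, each = length(mat$patient_ids)),
    tumor = as.vector(mat$tumor),
    nat = as.vector(mat$nat),
    stringsAsFactors = FALSE
  )
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_paired_abundance
#' @param epsilon Pseudocount for the reconstructed object.
#' @export
read_paired_abundance <- function(path, epsilon = 1) {
  long <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "protein_id", "tumor", "nat")
  if (!all(need %in% names(long)))
    stop("paired abundance TSV must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  pts <- unique(long$patient_id)
  prots <- unique(long$protein_id)
  shape <- function(col) {
    m <- matrix(NA_real_, length(pts), length(prots),
                dimnames = list(pts, prots))
    m[cbind(match(long$patient_id, pts), match(long$protein_id, prots))] <-
      long[[col]]
    m
  }
  paired_abundance(shape("tumor"), shape("nat"), pts, prots,
                   epsilon = epsilon)
}
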