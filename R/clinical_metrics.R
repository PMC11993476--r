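# Small defined clinical computations: IHC H-score, caliper tumor volume,
# chromosomal-instability classification, mutation-prevalence contingency.

#' IHC H-score
#'
#' Standard histoscore: `1 * pct_1 + 2 * pct_2 + 3 * pct_3`, where `pct_i`
#' is the percentage of cells staining at intensity i. Range 0 (all cells
#' negative) to 300 (all cells at intensity 3). Percentages must sum to 100.
#'
#' @param pct_0,pct_1,pct_2,pct_3 Percentages of cells at intensity 0-3.
#' @return H-score in `[0, 300]`.
#' @examples
#' h_score(10, 20, 30, 40)  # 200
#' @export
h_score <- function(pct_0, pct_1, pct_2, pct_3) {
  pct <- c(pct_0, pct_1, pct_2, pct_3)
  if (any(pct < 0 | pct > 100))
    stop("percentages must lie in [0, 100]", call. = FALSE)
  if (abs(sum(pct) - 100) > 1e-6)
    stop("intensity percentages must sum to 100 (got ", sum(pct), ")",
         call. = FALSE)
  1 * pct_1 + 2 * pct_2 + 3 * pct_3
}

#' Caliper tumor volume
#'
#' `volume (mm^3) = 0.5 * width^2 * length`, the standard two-dimensional
#' caliper formula. Width is the smaller of the two measurements; if the
#' arguments arrive swapped they are exchanged so the squared term is always
#' the smaller dimension.
#'
#' @param width,length_ Tumor width and length in mm (non-negative).
#' @return Volume in mm^3.
#' @examples
#' tumor_volume(10, 20)  # 1000
#' @export
tumor_volume <- function(width, length_) {
  if (any(c(width, length_) < 0))
    stop("tumor measurements must be non-negative", call. = FALSE)
  w <- pmin(width, length_)
  l <- pmax(width, length_)
  0.5 * w^2 * l
}

#' Chromosomal-instability (CIN) classification
#'
#' A sample is CIN if it is microsatellite stable (MSS) and its fraction of
#' genome altered (FGA) is at least 5% (inclusive threshold). FGA is
#' expected as a fraction in `[0, 1]`; values above 1 are auto-detected as
#' percentages and divided by 100, with a warning, to avoid the 5-vs-0.05
#' trap.
#'
#' @param msi_status `"MSS"` or `"MSI"`; vectorised.
#' @param fga Fraction of genome altered.
#' @return Logical: CIN or not.
#' @examples
#' classify_cin("MSS", 0.05)  # TRUE
#' classify_cin("MSI", 0.50)  # FALSE
#' @export
classify_cin <- function(msi_status, fga) {
  if (any(!msi_status %in% c("MSS", "MSI")))
    stop("msi_status must be 'MSS' or 'MSI'", call. = FALSE)
  if (any(fga < 0)) stop("fga must be non-negative", call. = FALSE)
  if (any(fga > 1)) {
    warning("fga > 1 interpreted as percent and divided by 100",
            call. = FALSE)
    fga <- ifelse(fga > 1, fga / 100, fga)
  }
  msi_status == "MSS" & fga >= 0.05
}

#' Mutation prevalence by group
#'
#' Builds the 2x2 contingency table of mutation status (for one gene)
#' against a two-level sample grouping, computes the odds ratio (with the
#' Haldane-Anscombe +0.5 correction when any cell is zero) and the
#' two-sided Fisher exact p-value.
#'
#' @param mutations Logical matrix (samples x genes) of mutation calls,
#'   with sample rownames and gene colnames.
#' @param groups Character/factor of group labels, one per sample (exactly
#'   two levels).
#' @param gene Gene to test (a column of `mutations`).
#' @return List: `table` (2x2: rows = groups, cols = mutated/wildtype),
#'   `odds_ratio`, `p_value`, `correction_applied`.
#' @export
mutation_prevalence_by_group <- function(mutations, groups, gene) {
  if (!gene %in% colnames(mutations))
    stop("unknown gene: ", gene, call. = FALSE)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L)
    stop("groups must have exactly two levels", call. = FALSE)
  if (any(table(groups) < 1L))
    stop("each group needs at least one sample", call. = FALSE)
  mut <- factor(mutations[, gene], levels = c(TRUE, FALSE),
                labels = c("mutated", "wildtype"))
  tab <- table(groups, mut)
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  corrected <- any(tab == 0)
  if (corrected) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  or <- (a * d) / (b * c)
  p <- stats::fisher.test(tab)$p.value
  list(table = tab, odds_ratio = unname(or), p_value = p,
       correction_applied = corrected)
}
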