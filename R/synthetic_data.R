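# Synthetic-data generators with planted ground truth. Every pipeline input
# can be produced here so each downstream stage is testable against known
# truth; fixed seed + config implies byte-identical output.

#' Generate paired tumor/NAT proteomics with planted differential proteins
#'
#' Log2 abundances are drawn per protein as Normal(baseline, `noise_sd`);
#' the planted differentially expressed proteins (DEPs) receive an additive
#' `effect_log2fc` in the tumor samples only. Matrices are returned on the
#' linear intensity scale. Membrane membership is sampled per protein at
#' `membrane_fraction`; the planted best target is guaranteed to be both a
#' DEP and a membrane protein.
#'
#' @param cfg A [sim_config].
#' @return A list with elements `mat` (a [paired_abundance]) and `truth`,
#'   where `truth` holds `true_dep_ids`, `true_membrane_ids`,
#'   `planted_best_target`, `planted_plateau`, and `planted_thinning`.
#' @examples
#' sim <- generate_paired_proteomics(sim_config(seed = 7, n_patients = 10,
#'                                              n_proteins = 20))
#' sim$truth$planted_best_target
#' @export
generate_paired_proteomics <- function(cfg) {
  validate_sim_config(cfg)
  set_op_seed(cfg$seed, "proteomics")
  n <- cfg$n_patients
  m <- cfg$n_proteins
  protein_ids <- sprintf("PROT%04d", seq_len(m))
  patient_ids <- sprintf("PT%03d", seq_len(n))

  baseline <- stats::rnorm(m, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
  log2_nat <- matrix(stats::rnorm(n * m, rep(baseline, each = n),
                                  cfg$noise_sd), n, m)
  log2_tum <- matrix(stats::rnorm(n * m, rep(baseline, each = n),
                                  cfg$noise_sd), n, m)

  dep_idx <- if (cfg$n_true_deps > 0) sample.int(m, cfg$n_true_deps)
             else integer(0)
  log2_tum[, dep_idx] <- log2_tum[, dep_idx] + cfg$effect_log2fc

  membrane <- stats::runif(m) < cfg$membrane_fraction
  best <- NA_character_
  if (length(dep_idx) > 0) {
    # planted best target: a DEP forced into the membrane set
    best_idx <- dep_idx[1L]
    membrane[best_idx] <- TRUE
    best <- protein_ids[best_idx]
  }

  mat <- paired_abundance(2^log2_tum, 2^log2_nat, patient_ids, protein_ids)
  truth <- list(
    true_dep_ids = protein_ids[sort(dep_idx)],
    true_membrane_ids = protein_ids[membrane],
    planted_best_target = best,
    planted_plateau = cfg$mfi_plateau,
    planted_thinning = c(a = cfg$thinning_a, tau = cfg$thinning_tau)
  )
  list(mat = mat, truth = truth)
}

#' Generate an ordinal normal-tissue expression table
#'
#' Draws one of the four ordinal levels (`not_detected` < `low` < `medium` <
#' `high`) per protein and tissue. `low_index_protein` is forced to
#' `not_detected` in every tissue while every other listed protein is
#' guaranteed at least one detected tissue, so the forced protein holds the
#' strictly minimal normal-tissue expression index among the candidates.
#'
#' @param cfg A [sim_config]; `n_tissues` sets the tissue count.
#' @param protein_ids Proteins to tabulate.
#' @param low_index_protein Protein forced to the minimal index; must be in
#'   `protein_ids`.
#' @param level_probs Sampling probabilities of the four levels, low to high.
#' @return A [tissue_expression_table].
#' @export
generate_tissue_table <- function(cfg, protein_ids, low_index_protein,
                                  level_probs = c(0.45, 0.3, 0.15, 0.1)) {
  validate_sim_config(cfg)
  if (!low_index_protein %in% protein_ids)
    stop("unknown protein id: ", low_index_protein, call. = FALSE)
  set_op_seed(cfg$seed, "tissue")
  nt <- cfg$n_tissues
  tissues <- sprintf("tissue_%02d", seq_len(nt))
  lv <- matrix(sample(0:3, length(protein_ids) * nt, replace = TRUE,
                      prob = level_probs),
               nrow = length(protein_ids),
               dimnames = list(protein_ids, tissues))
  lv[low_index_protein, ] <- 0L
  others <- setdiff(protein_ids, low_index_protein)
  zero_rows <- others[rowSums(lv[others, , drop = FALSE]) == 0]
  # guarantee strict minimality of the forced protein
  if (length(zero_rows) > 0) lv[zero_rows, 1L] <- 1L
  tissue_expression_table(lv)
}

#' Generate a surfaceome catalog from planted ground truth
#'
#' Wraps the planted membrane set into a catalog object, adding a lowercase
#' alias for a subset of entries to exercise case-insensitive alias
#' resolution downstream.
#'
#' @param truth Ground-truth list from [generate_paired_proteomics()].
#' @return A [surfaceome_catalog].
#' @export
generate_surfaceome <- function(truth) {
  ids <- truth$true_membrane_ids
  alias <- NULL
  if (length(ids) >= 3) {
    picked <- ids[seq_len(min(3L, length(ids)))]
    alias <- stats::setNames(picked, paste0(tolower(picked), "_alias"))
  }
  surfaceome_catalog(ids, alias_map = alias)
}

#' Generate a drug-target catalog with planted druggable DEPs
#'
#' A configurable fraction of the planted DEPs receive approved or
#' clinical-trial drugs (hence are recoverable by the payload screen);
#' additional random proteins receive preclinical-only records, which the
#' screen must exclude.
#'
#' @param cfg A [sim_config].
#' @param protein_ids All protein identifiers.
#' @param truth Ground-truth list from [generate_paired_proteomics()].
#' @param druggable_fraction Fraction of planted DEPs given a qualifying
#'   (approved/clinical-trial) drug.
#' @return A `data.frame` with columns `target_id`, `drug_name`, `phase`,
#'   `source_db`; `(target, drug, source)` triples are unique.
#' @export
generate_drug_catalog <- function(cfg, protein_ids, truth,
                                  druggable_fraction = 0.5) {
  validate_sim_config(cfg)
  set_op_seed(cfg$seed, "drugs")
  deps <- truth$true_dep_ids
  n_drug <- max(1L, round(druggable_fraction * length(deps)))
  druggable <- deps[seq_len(min(n_drug, length(deps)))]
  sources <- c("GDSC", "CTRP", "Repurposing")
  rows <- lapply(seq_along(druggable), function(i) {
    data.frame(
      target_id = druggable[i],
      drug_name = sprintf("drug_%s_%d", druggable[i], i),
      phase = sample(c("approved", "clinical_trial"), 1L),
      source_db = sample(sources, 1L),
      stringsAsFactors = FALSE
    )
  })
  # preclinical-only noise records on random non-DEP proteins
  pool <- setdiff(protein_ids, deps)
  n_pre <- min(10L, length(pool))
  pre <- data.frame(
    target_id = sample(pool, n_pre),
    drug_name = sprintf("preclin_%02d", seq_len(n_pre)),
    phase = "preclinical",
    source_db = sample(sources, n_pre, replace = TRUE),
    stringsAsFactors = FALSE
  )
  cat <- rbind(do.call(rbind, rows), pre)
  rownames(cat) <- NULL
  validate_drug_catalog(cat)
}

#' Generate an mIF cell map with optional planted depletion
#'
#' Source-phenotype cells follow a homogeneous Poisson process on the square
#' field. Target-phenotype cells are a Poisson process thinned by retention
#' `1 - a * exp(-d_min / tau)` where `d_min` is the distance to the nearest
#' source cell: targets are depleted near sources. Group `"high"` uses the
#' configured `(a, tau)`; group `"low"` uses `a = 0` (complete spatial
#' randomness).
#'
#' @param cfg A [sim_config].
#' @param group `"high"` or `"low"`.
#' @param sample_id Sample identifier recorded in the map.
#' @param seed Seed for this field; defaults to `cfg$seed`. Pass distinct
#'   values to simulate independent fields.
#' @param source_phenotype,target_phenotype Phenotype labels.
#' @return A [cell_map].
#' @export
generate_mif_cells <- function(cfg, group = c("high", "low"),
                               sample_id = "S1", seed = cfg$seed,
                               source_phenotype = "CD66c+",
                               target_phenotype = "CD138+") {
  validate_sim_config(cfg)
  group <- match.arg(group)
  set_op_seed(seed, "mif")
  L <- cfg$mif_field_size
  a <- if (group == "high") cfg$thinning_a else 0
  tau <- cfg$thinning_tau

  n_src <- stats::rpois(1L, cfg$mif_source_intensity * L^2)
  n_src <- max(n_src, 1L)  # proximity statistics need at least one source
  sx <- stats::runif(n_src, 0, L)
  sy <- stats::runif(n_src, 0, L)

  n_tgt <- stats::rpois(1L, cfg$mif_target_intensity * L^2)
  tx <- stats::runif(n_tgt, 0, L)
  ty <- stats::runif(n_tgt, 0, L)
  if (n_tgt > 0 && a > 0) {
    dmin <- nearest_distance(tx, ty, sx, sy)
    keep <- stats::runif(n_tgt) < 1 - a * exp(-dmin / tau)
    tx <- tx[keep]; ty <- ty[keep]
  }

  cell_map(data.frame(
    sample_id = sample_id,
    x_um = c(sx, tx),
    y_um = c(sy, ty),
    phenotypes = c(rep(source_phenotype, n_src),
                   rep(target_phenotype, length(tx))),
    stringsAsFactors = FALSE
  ))
}

#' Generate an antibody-internalization MFI time series
#'
#' Surface MFI decays as the bound antibody is endocytosed:
#' `MFI(t) = MFI0 * (1 - p * (1 - exp(-k t))) * (1 + eps)`, with
#' `eps ~ Normal(0, cv)` multiplicative noise and a noise-free anchor at
#' `t = 0`.
#'
#' @param cfg A [sim_config] supplying `mfi_baseline`, `mfi_plateau` (p),
#'   `mfi_rate` (k, 1/min) and `mfi_cv`.
#' @param times Measurement times in minutes; must include 0.
#' @param cell_line Label recorded on the series.
#' @return An [mfi_series].
#' @export
generate_mfi_series <- function(cfg, times = c(0, 30, 60, 120, 240),
                                cell_line = "synthetic") {
  validate_sim_config(cfg)
  if (!0 %in% times)
    stop("times must include 0 (the baseline measurement)", call. = FALSE)
  set_op_seed(cfg$seed, "mfi")
  times <- sort(unique(times))
  mu <- cfg$mfi_baseline *
    (1 - cfg$mfi_plateau * (1 - exp(-cfg$mfi_rate * times)))
  noise <- 1 + stats::rnorm(length(times), 0, cfg$mfi_cv)
  noise[times == 0] <- 1
  mfi_series(cell_line = cell_line, times = times, mfi = mu * noise)
}

#' Generate an immune cell-fraction table with a planted correlation
#'
#' Produces per-sample target expression plus deconvolution-style columns:
#' a `plasma_cells` fraction whose latent Gaussian is correlated with
#' expression at `cfg$assoc_r` (mapped to `[0, 0.2]` through the normal CDF,
#' a monotone transform that nearly preserves the Pearson correlation), two
#' uncorrelated immune fractions, and an unbounded `immune_score`.
#'
#' @param cfg A [sim_config].
#' @param n_samples Number of samples; defaults to `cfg$n_patients`.
#' @return A list with `expression` (named numeric) and `fractions`
#'   (a `data.frame` with rownames = sample ids and a `provenance`
#'   attribute).
#' @export
generate_fraction_table <- function(cfg, n_samples = cfg$n_patients) {
  validate_sim_config(cfg)
  set_op_seed(cfg$seed, "fractions")
  ids <- sprintf("S%03d", seq_len(n_samples))
  expr <- stats::rnorm(n_samples)
  r <- cfg$assoc_r
  latent <- r * expr + sqrt(1 - r^2) * stats::rnorm(n_samples)
  tab <- data.frame(
    plasma_cells = stats::pnorm(latent) * 0.2,
    b_cells = stats::pnorm(stats::rnorm(n_samples)) * 0.15,
    t_cells_cd8 = stats::pnorm(stats::rnorm(n_samples)) * 0.25,
    immune_score = stats::rnorm(n_samples, 0, 500),
    row.names = ids
  )
  attr(tab, "provenance") <- "synthetic-deconvolution"
  list(expression = stats::setNames(expr, ids), fractions = tab)
}

# Minimum distance from each (x, y) to the nearest of (sx, sy), chunked to
# bound memory for large maps.
nearest_distance <- function(x, y, sx, sy, chunk = 2048L) {
  n <- length(x)
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    d2 <- outer(x[idx], sx, "-")^2 + outer(y[idx], sy, "-")^2
    out[idx] <- sqrt(apply(d2, 1L, min))
  }
  out
}
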