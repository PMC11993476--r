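# Configuration-driven orchestration of all stages on synthetic or
# user-supplied inputs, with provenance records and deterministic reruns.

#' Default pipeline configuration
#'
#' Flat named list understood by [run_pipeline()]. `sim` holds the
#' synthetic-data parameters (see [sim_config()]); stage thresholds mirror
#' the module defaults. Any field can be overridden via `overrides` or a
#' YAML file ([read_pipeline_config()]).
#'
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @param overrides Named list of fields to override (nested under `sim`
#'   for generator parameters).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("adcscreen_"),
                            overrides = list()) {
  cfg <- list(
    seed = seed,
    out_dir = out_dir,
    stages = c("simulate", "diffexp", "nominate_targets",
               "nominate_payloads", "internalization", "spatial",
               "associate"),
    top_k = 20L,
    q_threshold = 0.05,
    payload_k = 10L,
    bin_edges = c(0, 50, 100, 150, 200),
    n_mif_per_group = 10L,
    tissue_table = NULL,      # path to an external tissue table (optional)
    proteomics = NULL,        # path to an external paired-abundance TSV
    surfaceome = NULL,        # path to an external catalog
    drug_catalog = NULL,      # path to an external drug catalog CSV
    sim = unclass(sim_config(seed = seed))
  )
  for (nm in names(overrides)) {
    if (nm == "sim") {
      for (s in names(overrides$sim)) cfg$sim[[s]] <- overrides$sim[[s]]
    } else cfg[[nm]] <- overrides[[nm]]
  }
  cfg$sim$seed <- cfg$seed
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys as in [pipeline_config()].
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- if (!is.null(y$seed)) y$seed else 1L
  out <- if (!is.null(y$out_dir)) y$out_dir else tempfile("adcscreen_")
  y$seed <- NULL; y$out_dir <- NULL
  pipeline_config(seed = seed, out_dir = out, overrides = y)
}

validate_pipeline_config <- function(cfg) {
  if (!inherits(cfg, "pipeline_config"))
    stop("cfg must be a pipeline_config", call. = FALSE)
  for (f in c("tissue_table", "proteomics", "surfaceome", "drug_catalog")) {
    p <- cfg[[f]]
    if (!is.null(p) && !file.exists(p))
      stop("configured input file does not exist: ", f, " = ", p,
           call. = FALSE)
  }
  if (cfg$q_threshold <= 0 || cfg$q_threshold > 1)
    stop("q_threshold must lie in (0, 1]", call. = FALSE)
  if (cfg$top_k < 1 || cfg$payload_k < 1)
    stop("top_k and payload_k must be >= 1", call. = FALSE)
  do.call(sim_config, cfg$sim)  # re-validates generator parameters
  invisible(cfg)
}

pipeline_log <- function(level, ...) {
  message(sprintf("[adcscreen] %s %s", level, paste0(...)))
}

#' Run the full nomination pipeline
#'
#' Executes the enabled stages in dependency order: simulate (or load)
#' inputs, paired differential test, target nomination, payload screen,
#' internalization kinetics, spatial proximity statistics, and immune
#' association. Every stage writes its artifact under `cfg$out_dir`, and a
#' `provenance.json` records the configuration, seed, package and R
#' versions, and the MD5 checksum of every output, so a rerun with the same
#' configuration and seed is bit-identical.
#'
#' @param cfg A `pipeline_config` (validated before any stage runs).
#' @return Invisibly, a list with the `nomination` report, `payloads`
#'   ranking, per-stage results, and `artifacts` (named file paths).
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  validate_pipeline_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  scfg <- do.call(sim_config, cfg$sim)
  artifacts <- character(0)
  results <- list()
  stage_on <- function(s) s %in% cfg$stages
  save_artifact <- function(name, path) {
    artifacts[[name]] <<- path
  }
  run_stage <- function(name, fun) {
    pipeline_log("INFO", "stage ", name, " started")
    tryCatch(fun(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # -- simulate / load inputs ----------------------------------------------
  sim <- NULL
  if (!is.null(cfg$proteomics)) {
    mat <- read_paired_abundance(cfg$proteomics)
    truth <- NULL
  } else {
    sim <- run_stage("simulate", function() generate_paired_proteomics(scfg))
    mat <- sim$mat
    truth <- sim$truth
    if (stage_on("simulate")) {
      p <- file.path(cfg$out_dir, "paired_abundance.tsv")
      write_paired_abundance(mat, p)
      save_artifact("paired_abundance", p)
      gt <- file.path(cfg$out_dir, "ground_truth.json")
      jsonlite::write_json(truth, gt, auto_unbox = TRUE, digits = NA)
      save_artifact("ground_truth", gt)
    }
  }
  catalog <- if (!is.null(cfg$surfaceome)) read_surfaceome(cfg$surfaceome)
             else if (!is.null(truth)) generate_surfaceome(truth)
             else stop("a surfaceome catalog path is required when ",
                       "proteomics are supplied externally", call. = FALSE)
  drug_cat <- if (!is.null(cfg$drug_catalog))
                read_drug_catalog(cfg$drug_catalog)
              else if (!is.null(truth))
                generate_drug_catalog(scfg, mat$protein_ids, truth)
              else stop("a drug catalog path is required when ",
                        "proteomics are supplied externally", call. = FALSE)

  # -- differential expression ---------------------------------------------
  diff <- run_stage("diffexp", function() paired_differential_test(mat))
  if (stage_on("diffexp")) {
    p <- file.path(cfg$out_dir, "diffexp.tsv")
    write_diff_table(diff, p)
    save_artifact("diffexp", p)
  }
  fc <- per_patient_log2fc(mat)

  # -- target nomination ----------------------------------------------------
  nomination <- NULL
  if (stage_on("nominate_targets")) {
    tissue <- if (!is.null(cfg$tissue_table)) read_tissue_table(cfg$tissue_table)
      else {
        best <- if (!is.null(truth)) truth$planted_best_target
                else mat$protein_ids[1L]
        generate_tissue_table(scfg, mat$protein_ids, best)
      }
    nomination <- run_stage("nominate_targets", function()
      nominate_targets(diff, catalog, tissue, fc, k = cfg$top_k))
    p <- file.path(cfg$out_dir, "nomination.tsv")
    utils::write.table(nomination, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    save_artifact("nomination", p)
    results$nomination <- nomination
  }

  # -- payload screen -------------------------------------------------------
  payloads <- NULL
  if (stage_on("nominate_payloads")) {
    noms <- run_stage("nominate_payloads", function()
      druggable_deps(diff, drug_cat, q_threshold = cfg$q_threshold))
    payloads <- rank_payload_targets(noms, k = cfg$payload_k)
    p <- file.path(cfg$out_dir, "payloads.tsv")
    utils::write.table(payloads, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    save_artifact("payloads", p)
    results$payloads <- payloads
    results$payload_counts <- c(n_targets = attr(noms, "n_targets"),
                                n_pairs = attr(noms, "n_pairs"))
  }

  # -- internalization kinetics --------------------------------------------
  if (stage_on("internalization")) {
    curve <- run_stage("internalization", function()
      build_curve(generate_mfi_series(scfg)))
    p <- file.path(cfg$out_dir, "internalization.json")
    jsonlite::write_json(
      list(cell_line = curve$cell_line, times = curve$times,
           efficiency = curve$efficiency,
           plateau_empirical = curve$plateau_empirical, fit = curve$fit),
      p, auto_unbox = TRUE, digits = NA)
    save_artifact("internalization", p)
    results$internalization <- curve
  }

  # -- spatial proximity ----------------------------------------------------
  if (stage_on("spatial")) {
    spatial <- run_stage("spatial", function() {
      bins <- radial_bins(cfg$bin_edges)
      per_group <- lapply(c(high = "high", low = "low"), function(g) {
        vapply(seq_len(cfg$n_mif_per_group), function(i) {
          map <- generate_mif_cells(scfg, group = g,
                                    sample_id = sprintf("%s_%02d", g, i),
                                    seed = scfg$seed + i +
                                      if (g == "high") 0L else 5000L)
          radial_bin_counts(map, "CD66c+", "CD138+", bins)[1L]
        }, numeric(1))
      })
      cmp <- compare_groups(per_group$high, per_group$low)
      list(first_bin_counts = per_group, comparison = cmp)
    })
    p <- file.path(cfg$out_dir, "spatial.json")
    jsonlite::write_json(spatial, p, auto_unbox = TRUE, digits = NA)
    save_artifact("spatial", p)
    results$spatial <- spatial
  }

  # -- immune association ---------------------------------------------------
  if (stage_on("associate")) {
    assoc <- run_stage("associate", function() {
      ft <- generate_fraction_table(scfg)
      associate_expression_with_fractions(ft$expression, ft$fractions)
    })
    p <- file.path(cfg$out_dir, "association.tsv")
    utils::write.table(assoc, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    save_artifact("association", p)
    results$association <- assoc
  }

  # -- provenance -----------------------------------------------------------
  prov <- list(
    package = "adcscreen",
    package_version = as.character(utils::packageVersion("adcscreen")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    config = unclass(cfg)[setdiff(names(cfg), "out_dir")],
    artifact_md5 = as.list(tools::md5sum(unlist(artifacts)))
  )
  pp <- file.path(cfg$out_dir, "provenance.json")
  jsonlite::write_json(prov, pp, auto_unbox = TRUE, digits = NA)
  artifacts[["provenance"]] <- pp

  results$artifacts <- artifacts
  pipeline_log("INFO", "pipeline finished: ", length(artifacts),
               " artifact(s) in ", cfg$out_dir)
  invisible(results)
}
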