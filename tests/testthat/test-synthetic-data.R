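test_that("generators are deterministic under a fixed seed", {
  cfg <- default_cfg(seed = 7, n_patients = 20, n_proteins = 30)
  a <- generate_paired_proteomics(cfg)
  b <- generate_paired_proteomics(cfg)
  expect_identical(a$mat$tumor, b$mat$tumor)
  expect_identical(a$mat$nat, b$mat$nat)
  expect_identical(a$truth, b$truth)

  t1 <- generate_tissue_table(cfg, a$mat$protein_ids,
                              a$truth$planted_best_target)
  t2 <- generate_tissue_table(cfg, a$mat$protein_ids,
                              a$truth$planted_best_target)
  expect_identical(t1$levels, t2$levels)

  m1 <- generate_mif_cells(cfg, "high")
  m2 <- generate_mif_cells(cfg, "high")
  expect_identical(m1$cells, m2$cells)

  s1 <- generate_mfi_series(cfg)
  s2 <- generate_mfi_series(cfg)
  expect_identical(s1$mfi, s2$mfi)

  f1 <- generate_fraction_table(cfg)
  f2 <- generate_fraction_table(cfg)
  expect_identical(f1$fractions, f2$fractions)
})

test_that("invalid configurations raise errors naming the offending field", {
  expect_error(sim_config(n_true_deps = 50, n_proteins = 10),
               "n_true_deps")
  expect_error(sim_config(membrane_fraction = 1.5), "membrane_fraction")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(thinning_a = 2), "thinning_a")
})

test_that("null effect produces no systematic tumor-NAT difference", {
  cfg <- default_cfg(seed = 11, effect_log2fc = 0, n_patients = 100,
                     n_proteins = 100)
  sim <- generate_paired_proteomics(cfg)
  d <- log2(sim$mat$tumor) - log2(sim$mat$nat)
  se <- cfg$noise_sd * sqrt(2) / sqrt(cfg$n_patients)
  # max |z| over 100 null proteins stays below a generous Gaussian bound
  expect_lt(max(abs(colMeans(d))) / se, 6)
})

test_that("planted effect is recovered by direct simulation at large n", {
  cfg <- default_cfg(seed = 1, n_true_deps = 10, effect_log2fc = 2,
                     noise_sd = 0.5, n_patients = 100)
  sim <- generate_paired_proteomics(cfg)
  d <- log2(sim$mat$tumor) - log2(sim$mat$nat)
  se <- cfg$noise_sd * sqrt(2) / sqrt(cfg$n_patients)
  for (id in sim$truth$true_dep_ids) {
    expect_lt(abs(mean(d[, id]) - 2), 2 * se)
  }
  # pairing: planted best target is a membrane DEP
  expect_true(sim$truth$planted_best_target %in% sim$truth$true_dep_ids)
  expect_true(sim$truth$planted_best_target %in%
                sim$truth$true_membrane_ids)
})

test_that("tissue generator forces a strictly minimal index", {
  cfg <- default_cfg(seed = 3, n_proteins = 30)
  sim <- generate_paired_proteomics(cfg)
  ids <- sim$mat$protein_ids
  best <- sim$truth$planted_best_target
  tab <- generate_tissue_table(cfg, ids, best)
  idx <- vapply(ids, function(p) normal_tissue_index(tab, p), integer(1))
  expect_identical(unname(idx[best]), 0L)
  expect_true(all(idx[setdiff(ids, best)] > 0))
  expect_true(all(idx >= 0 & idx <= 3 * cfg$n_tissues))
  expect_error(generate_tissue_table(cfg, ids, "NOT_A_PROTEIN"),
               "unknown protein")
})

test_that("mIF thinning depletes targets near sources", {
  cfg <- default_cfg(mif_field_size = 600)
  edges <- c(0, 50, 150, 200)
  ratios <- vapply(1:200, function(i) {
    hi <- generate_mif_cells(cfg, "high", seed = 1000 + i)
    lo <- generate_mif_cells(cfg, "low", seed = 1000 + i)
    ch <- radial_bin_counts(hi, "CD66c+", "CD138+", radial_bins(edges))
    cl <- radial_bin_counts(lo, "CD66c+", "CD138+", radial_bins(edges))
    c(near = ch[[1]] / max(cl[[1]], 1), far = ch[[3]] / max(cl[[3]], 1))
  }, numeric(2))
  # mean retained fraction near sources < in the 150-200 um band
  expect_lt(mean(ratios["near", ]), mean(ratios["far", ]))
})

test_that("MFI generator honors its limits", {
  cfg0 <- default_cfg(mfi_plateau = 0, mfi_cv = 0.01)
  s <- generate_mfi_series(cfg0)
  expect_true(all(abs(s$mfi / s$mfi[1] - 1) < 0.05))

  cfg <- default_cfg(mfi_plateau = 0.4, mfi_rate = 0.02, mfi_cv = 0)
  s <- generate_mfi_series(cfg, times = c(0, 60, 1e5))
  expect_equal(s$mfi[3] / s$mfi[1], 1 - 0.4, tolerance = 1e-8)

  expect_error(generate_mfi_series(cfg, times = c(30, 60)), "include 0")
})

test_that("generated tables round-trip through writers and readers", {
  cfg <- default_cfg(seed = 5, n_patients = 6, n_proteins = 8,
                     n_true_deps = 4)
  sim <- generate_paired_proteomics(cfg)
  tmp <- withr::local_tempdir()

  p1 <- file.path(tmp, "pa.tsv")
  write_paired_abundance(sim$mat, p1)
  back <- read_paired_abundance(p1)
  expect_equal(back$tumor, sim$mat$tumor, tolerance = 1e-12)
  expect_equal(back$nat, sim$mat$nat, tolerance = 1e-12)

  tab <- generate_tissue_table(cfg, sim$mat$protein_ids,
                               sim$truth$planted_best_target)
  p2 <- file.path(tmp, "tissue.tsv")
  write_tissue_table(tab, p2)
  expect_identical(read_tissue_table(p2)$levels, tab$levels)

  catalog <- generate_surfaceome(sim$truth)
  p3 <- file.path(tmp, "surf.txt")
  write_surfaceome(catalog, p3)
  expect_identical(read_surfaceome(p3)$membrane_ids, catalog$membrane_ids)

  dc <- generate_drug_catalog(cfg, sim$mat$protein_ids, sim$truth)
  p4 <- file.path(tmp, "drugs.csv")
  write_drug_catalog(dc, p4)
  expect_identical(read_drug_catalog(p4), validate_drug_catalog(dc))

  map <- generate_mif_cells(cfg, "high")
  p5 <- file.path(tmp, "cells.csv")
  write_cell_table(map, p5)
  back_map <- read_cell_table(p5)
  expect_equal(back_map$cells$x_um, map$cells$x_um, tolerance = 1e-9)
  expect_identical(back_map$cells$phenotypes, map$cells$phenotypes)
})
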