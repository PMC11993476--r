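test_that("membrane filter intersects case-insensitively with aliases", {
  cat <- surfaceome_catalog(c("B", "C", "D"))
  expect_identical(membrane_filter(c("A", "B", "C"), cat), c("B", "C"))
  expect_identical(membrane_filter(c("A", "B"), surfaceome_catalog(character(0))),
                   character(0))
  cat2 <- surfaceome_catalog("CD66C", alias_map = c(CEACAM6 = "CD66C"))
  expect_identical(membrane_filter("ceacam6", cat2), "ceacam6")
  # order preserved
  expect_identical(membrane_filter(c("C", "B"), cat), c("C", "B"))
})

test_that("ordinal level parsing is case-insensitive and strict", {
  expect_identical(parse_expression_level(c("High", "not detected", "LOW",
                                            "Medium", "nd")),
                   c(3L, 0L, 1L, 2L, 0L))
  expect_error(parse_expression_level("sorta high"), "unknown expression")
  expect_error(parse_expression_level(c(0, 5)), "0..3")
})

test_that("normal-tissue index reproduces its arithmetic examples", {
  nd <- matrix(0L, 1, 41, dimnames = list("P1", NULL))
  expect_identical(normal_tissue_index(tissue_expression_table(nd), "P1"), 0L)

  hi <- matrix(3L, 1, 41, dimnames = list("P2", NULL))
  expect_identical(normal_tissue_index(tissue_expression_table(hi), "P2"),
                   123L)

  mixed <- matrix(c(rep(3L, 5), rep(2L, 3), rep(1L, 2), rep(0L, 31)), 1, 41,
                  dimnames = list("P3", NULL))
  expect_identical(normal_tissue_index(tissue_expression_table(mixed), "P3"),
                   23L)

  expect_error(normal_tissue_index(tissue_expression_table(hi), "NOPE"),
               "unknown protein")
})

test_that("normal-tissue index is invariant to tissue permutation", {
  set.seed(6)
  for (i in 1:10) {
    lv <- matrix(sample(0:3, 41, replace = TRUE), 1, 41,
                 dimnames = list("P", paste0("t", 1:41)))
    perm <- lv[, sample(41), drop = FALSE]
    expect_identical(
      normal_tissue_index(tissue_expression_table(lv), "P"),
      normal_tissue_index(tissue_expression_table(perm), "P")
    )
  }
})

test_that("specificity profile uses strict wins and the patient median", {
  fc <- cbind(cand = c(2, 3, 4), ref = c(1, 1, 1))
  prof <- specificity_profile(fc, "cand", "ref")
  expect_equal(prof$win_fraction_vs_refs[["ref"]], 1)
  expect_equal(prof$specificity_median, 3)

  fc_tie <- cbind(cand = c(1, 2), ref = c(1, 2))
  expect_equal(
    specificity_profile(fc_tie, "cand", "ref")$win_fraction_vs_refs[["ref"]],
    0)  # ties do not credit the candidate

  expect_error(specificity_profile(fc, "cand", "missing"), "absent")
})

test_that("win fractions match a brute-force pairwise count", {
  set.seed(12)
  n <- 200
  fc <- matrix(rnorm(n * 4), n, 4,
               dimnames = list(NULL, c("cand", "r1", "r2", "r3")))
  prof <- specificity_profile(fc, "cand", c("r1", "r2", "r3"))
  for (r in c("r1", "r2", "r3")) {
    wins <- 0L
    for (i in seq_len(n)) if (fc[i, "cand"] > fc[i, r]) wins <- wins + 1L
    expect_equal(prof$win_fraction_vs_refs[[r]], wins / n)
  }
})

test_that("nomination ranks the planted best target first on synthetic data", {
  cfg <- default_cfg(seed = 1)
  sim <- generate_paired_proteomics(cfg)
  diff <- paired_differential_test(sim$mat)
  catalog <- generate_surfaceome(sim$truth)
  tissue <- generate_tissue_table(cfg, sim$mat$protein_ids,
                                  sim$truth$planted_best_target)
  fc <- per_patient_log2fc(sim$mat)
  rep <- nominate_targets(diff, catalog, tissue, fc, k = 20)
  expect_identical(rep$protein_id[1], sim$truth$planted_best_target)
  expect_identical(rep$rank, seq_len(nrow(rep)))
  # membrane subset size matches the brute-force intersection
  top <- top_k_deps(diff, 20, "up")
  brute <- sum(toupper(top) %in% catalog$membrane_ids)
  expect_identical(nrow(rep), brute)
})

test_that("nomination tie-breaks on specificity then id, and ignores input order", {
  diff <- data.frame(
    protein_id = c("AA", "BB", "CC"),
    log2fc = c(2, 1, 1.5),
    p_value = c(1e-5, 1e-4, 5e-5),
    q_value = c(3e-5, 1e-4, 7e-5),
    rank = NA_integer_, n_pairs = 10L, tested = TRUE,
    stringsAsFactors = FALSE
  )
  class(diff) <- c("diff_expression_table", "data.frame")
  catalog <- surfaceome_catalog(c("AA", "BB", "CC"))
  lv <- matrix(1L, 3, 5, dimnames = list(c("AA", "BB", "CC"), NULL))
  tissue <- tissue_expression_table(lv)  # equal nt_index everywhere
  fc <- cbind(AA = rep(2, 4), BB = rep(1, 4), CC = rep(1.5, 4))
  rep1 <- nominate_targets(diff, catalog, tissue, fc, k = 3)
  expect_identical(rep1$protein_id, c("AA", "CC", "BB"))  # by specificity

  perm <- diff[c(3, 1, 2), ]
  class(perm) <- c("diff_expression_table", "data.frame")
  rep2 <- nominate_targets(perm, catalog, tissue, fc, k = 3)
  expect_identical(rep2$protein_id, rep1$protein_id)
})

test_that("empty membrane intersection yields an empty report with warning", {
  diff <- data.frame(
    protein_id = "AA", log2fc = 2, p_value = 1e-5, q_value = 3e-5,
    rank = 1L, n_pairs = 10L, tested = TRUE, stringsAsFactors = FALSE
  )
  class(diff) <- c("diff_expression_table", "data.frame")
  tissue <- tissue_expression_table(
    matrix(1L, 1, 5, dimnames = list("AA", NULL)))
  fc <- cbind(AA = rep(2, 4))
  expect_warning(
    rep <- nominate_targets(diff, surfaceome_catalog("ZZ"), tissue, fc,
                            k = 1),
    "no membrane"
  )
  expect_identical(nrow(rep), 0L)
})
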