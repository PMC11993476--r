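simple_map <- function(x, y, ph, sample_id = "S1") {
  cell_map(data.frame(sample_id = sample_id, x_um = x, y_um = y,
                      phenotypes = ph, stringsAsFactors = FALSE))
}

test_that("phenotype proportion covers its boundary cases", {
  m <- simple_map(1:4, 1:4, rep("A+", 4))
  expect_equal(phenotype_proportion(m, "A+"), 1)
  expect_equal(phenotype_proportion(m, "B+"), 0)
  m2 <- simple_map(1:8, 1:8, c(rep("A+", 2), rep("B+", 6)))
  expect_equal(phenotype_proportion(m2, "A+"), 0.25)
  empty <- cell_map(data.frame(sample_id = character(0),
                               x_um = numeric(0), y_um = numeric(0),
                               phenotypes = character(0),
                               stringsAsFactors = FALSE))
  expect_error(phenotype_proportion(empty, "A+"), "empty")
})

test_that("radial binning places known geometries correctly", {
  # 3-4-5 triangle: distance 5 -> first band
  m <- simple_map(c(0, 3), c(0, 4), c("SRC+", "TGT+"))
  counts <- radial_bin_counts(m, "SRC+", "TGT+")
  expect_identical(unname(unclass(counts)[1:4]), c(1L, 0L, 0L, 0L))

  # exactly 50 um falls in the 50-100 band (half-open bins)
  m2 <- simple_map(c(0, 30), c(0, 40), c("SRC+", "TGT+"))
  counts2 <- radial_bin_counts(m2, "SRC+", "TGT+")
  expect_identical(unname(unclass(counts2)[1:4]), c(0L, 1L, 0L, 0L))

  # beyond the last edge: uncounted but conserved
  m3 <- simple_map(c(0, 500), c(0, 0), c("SRC+", "TGT+"))
  counts3 <- radial_bin_counts(m3, "SRC+", "TGT+")
  expect_identical(sum(counts3), 0L)
  expect_identical(attr(counts3, "n_beyond"), 1L)

  # co-labeled cells are excluded from targets
  m4 <- simple_map(c(0, 10), c(0, 0), c("SRC+;TGT+", "TGT+"))
  counts4 <- radial_bin_counts(m4, "SRC+", "TGT+")
  expect_identical(attr(counts4, "n_excluded"), 1L)
  expect_identical(sum(counts4), 1L)

  expect_error(radial_bin_counts(m, "NOPE+", "TGT+"), "no source")
  expect_error(radial_bins(c(0, 50, 50)), "strictly increasing")
})

test_that("bin counts satisfy conservation on random maps", {
  cfg <- default_cfg(mif_field_size = 400)
  for (i in 1:10) {
    map <- generate_mif_cells(cfg, "high", seed = 100 + i)
    counts <- radial_bin_counts(map, "CD66c+", "CD138+")
    expect_identical(
      sum(counts) + attr(counts, "n_beyond") + attr(counts, "n_excluded"),
      attr(counts, "n_targets")
    )
  }
})

test_that("bin counts are invariant under rotation and translation", {
  cfg <- default_cfg(mif_field_size = 400)
  map <- generate_mif_cells(cfg, "high", seed = 99)
  counts <- radial_bin_counts(map, "CD66c+", "CD138+")
  theta <- 0.7; dx <- 123.4; dy <- -55.5
  cells <- map$cells
  x2 <- cos(theta) * cells$x_um - sin(theta) * cells$y_um + dx
  y2 <- sin(theta) * cells$x_um + cos(theta) * cells$y_um + dy
  moved <- simple_map(x2, y2, cells$phenotypes)
  expect_identical(unclass(radial_bin_counts(moved, "CD66c+", "CD138+"))[1:4],
                   unclass(counts)[1:4])
})

test_that("bin counts equal the O(n^2) all-pairs oracle", {
  set.seed(31)
  n <- 500
  cells <- data.frame(
    sample_id = "S",
    x_um = runif(n, 0, 600), y_um = runif(n, 0, 600),
    phenotypes = sample(c("SRC+", "TGT+", "SRC+;TGT+", "OTHER"), n,
                        replace = TRUE, prob = c(0.3, 0.5, 0.05, 0.15)),
    stringsAsFactors = FALSE
  )
  edges <- c(0, 50, 100, 150, 200)
  counts <- radial_bin_counts(cell_map(cells), "SRC+", "TGT+",
                              radial_bins(edges))
  expect_identical(unname(unclass(counts)[1:4]),
                   radial_counts_oracle(cells, "SRC+", "TGT+", edges))
})

test_that("median dichotomization uses a strict cut at the median", {
  v <- c(a = 1, b = 2, c = 3, d = 4)
  g <- dichotomize_samples(v)
  expect_identical(names(g[g == "high"]), c("c", "d"))
  # value equal to the median goes low
  v2 <- c(1, 2, 3)
  expect_identical(unname(dichotomize_samples(v2)), c("low", "low", "high"))
  expect_warning(g3 <- dichotomize_samples(c(2, 2, 2)), "identical")
  expect_true(all(g3 == "low"))
  set.seed(13)
  for (i in 1:20) {
    x <- rnorm(sample(4:30, 1))
    expect_identical(unname(dichotomize_samples(x)), dichotomize_oracle(x))
  }
})

test_that("group comparison handles identical and degenerate inputs", {
  res <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$mean_difference, 0)

  degen <- compare_groups(c(5, 5), c(5, 5))
  expect_true(degen$degenerate)
  expect_true(is.na(degen$p_value))
  expect_equal(degen$mean_difference, 0)

  # permutation of labels preserves the pooled mean
  set.seed(17)
  x <- rnorm(10); y <- rnorm(8)
  pooled <- mean(c(x, y))
  idx <- sample(18, 10)
  z <- c(x, y)
  expect_equal(mean(c(z[idx], z[-idx])), pooled)
  r <- compare_groups(z[idx], z[-idx])
  expect_equal((sum(z[idx]) + sum(z[-idx])) / 18, pooled)
})

test_that("mann-whitney option runs and detects a location shift", {
  set.seed(23)
  res <- compare_groups(rnorm(30, 2), rnorm(30, 0), method = "mann_whitney")
  expect_lt(res$p_value, 0.01)
  expect_gt(res$mean_difference, 1)
})
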