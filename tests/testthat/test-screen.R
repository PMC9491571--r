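test_that("pearson_r matches hand-computed values and flags degeneracy", {
  expect_equal(pearson_r(1:5, 1:5), 1, ignore_attr = TRUE)
  expect_equal(pearson_r(c(1, 2, 3), c(6, 4, 2)), -1, ignore_attr = TRUE)
  # centered cross-product 4 over sqrt(5 * 5)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8, ignore_attr = TRUE)
  deg <- pearson_r(c(2, 2, 2), c(1, 5, 9))
  expect_equal(as.numeric(deg), 0)
  expect_true(attr(deg, "degenerate"))
  expect_false(attr(pearson_r(1:4, 4:1), "degenerate"))
  expect_error(pearson_r(1:4, 1:5), "equal length")
  expect_error(pearson_r(1:2, 1:2), "3 observations")
})

test_that("pearson_r is affine invariant up to sign", {
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(15); y <- rnorm(15)
    a <- runif(1, -5, 5); c_ <- runif(1, -5, 5)
    if (abs(a) < 1e-3 || abs(c_) < 1e-3) next
    r0 <- as.numeric(pearson_r(x, y))
    r1 <- as.numeric(pearson_r(a * x + runif(1), c_ * y - runif(1)))
    expect_equal(r1, sign(a * c_) * r0, tolerance = 1e-12)
  }
})

test_that("the screen agrees with a direct per-resample correlation oracle", {
  co <- small_cohort()
  design <- small_design(co, n_resamples = 20)
  sc <- run_screen(co$expression, design, "RSPO3")
  # naive oracle: explicit cor() per gene and per resample set
  for (g in sample(rownames(co$expression), 12)) {
    rs <- vapply(design$resample_sets, function(set) {
      ids <- c(design$case_ids, set)
      xg <- co$expression[g, ids]; xr <- co$expression["RSPO3", ids]
      if (sd(xg) == 0 || sd(xr) == 0) 0 else cor(xg, xr)
    }, numeric(1))
    row <- sc[sc$gene_id == g, ]
    expect_equal(row$median_abs_r, median(abs(rs)), tolerance = 1e-10,
                 label = g)
    expect_equal(row$median_signed_r, median(rs), tolerance = 1e-10, label = g)
  }
})

test_that("screen ranks the reference first and handles degenerate genes", {
  co <- small_cohort()
  design <- small_design(co)
  sc <- run_screen(co$expression, design, "RSPO3")
  ref <- sc[sc$gene_id == "RSPO3", ]
  expect_equal(ref$median_abs_r, 1)
  expect_equal(ref$rank, 1L)
  zero_gene <- co$truth$gene_id[co$truth$is_zero][1]
  zr <- sc[sc$gene_id == zero_gene, ]
  expect_true(zr$degenerate)
  expect_equal(zr$median_abs_r, 0)
  expect_equal(zr$direction, "flat")
  # planted module genes carry real signal and are selected at 0.2
  mod <- co$truth$gene_id[!is.na(co$truth$module)]
  mod_r <- sc$median_abs_r[sc$gene_id %in% mod]
  expect_true(all(mod_r > 0.2 & mod_r <= 1))
  expect_true(all(mod %in% select_genes(sc, 0.2)))
  # ranking is decreasing with lexicographic tie-break
  expect_true(all(diff(sc$median_abs_r) <= 0))
})

test_that("selection uses a strict cutoff and nests across cutoffs", {
  records <- tibble::tibble(
    gene_id = c("A", "B", "C", "D"),
    median_abs_r = c(0.5, 0.21, 0.2, 0.1),
    median_signed_r = c(0.5, 0.21, -0.2, 0.1),
    rank = 1:4)
  expect_equal(select_genes(records, 0.2), c("A", "B"))
  expect_equal(select_genes(records, 0), c("A", "B", "C", "D"))
  expect_error(select_genes(records, 1.5), "cutoff")

  co <- small_cohort()
  sc <- run_screen(co$expression, small_design(co), "RSPO3")
  s05 <- select_genes(sc, 0.5)
  s02 <- select_genes(sc, 0.2)
  expect_true(all(s05 %in% s02))
})

test_that("z-score matrix follows the documented sample-SD convention", {
  m <- matrix(c(1, 2, 3, 5, 5, 5), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("a", "b", "c")))
  z <- zscore_matrix(m)
  expect_equal(unname(z["g1", ]), c(-1, 0, 1))
  expect_equal(unname(z["g2", ]), c(0, 0, 0))
  # every non-constant row standardized
  co <- small_cohort()
  z2 <- zscore_matrix(co$expression, genes = c("RSPO3", "PTPRK"))
  expect_equal(unname(rowMeans(z2)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(z2, 1, sd)), c(1, 1), tolerance = 1e-12)
  expect_error(zscore_matrix(m, genes = character(0)), "empty")
  expect_error(zscore_matrix(m, genes = "nope"), "absent")
})
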