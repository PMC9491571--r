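test_that("tumor filtering reproduces the sample funnel and is idempotent", {
  md <- tibble::tibble(
    sample_id = sprintf("S%03d", 1:433),
    sample_type = rep(c("tumor", "normal", "metastasis"), c(379, 53, 1)))
  tumors <- filter_tumor_samples(md)
  expect_length(tumors, 379)
  expect_identical(filter_tumor_samples(md[md$sample_id %in% tumors, ]), tumors)
  expect_length(filter_tumor_samples(md[md$sample_type == "normal", ]), 0)
})

test_that("case selection requires both the fusion call and elevation", {
  co <- small_cohort()
  tumors <- filter_tumor_samples(co$metadata)
  cases <- select_cases(co$fusion_calls, co$expression, "RSPO3", tumors)
  expect_setequal(cases, co$fusion_calls$sample_id)

  # a call on a below-median sample is dropped by the elevation rule
  ref <- co$expression["RSPO3", tumors]
  low_sample <- tumors[which.min(ref)]
  fus2 <- dplyr::bind_rows(co$fusion_calls,
                           tibble::tibble(sample_id = low_sample,
                                          gene_5prime = "PTPRK",
                                          gene_3prime = "RSPO3"))
  cases2 <- select_cases(fus2, co$expression, "RSPO3", tumors)
  expect_false(low_sample %in% cases2)
  expect_setequal(cases2, cases)
  # but kept when the elevation rule is disabled
  cases3 <- select_cases(fus2, co$expression, "RSPO3", tumors,
                         elevation_rule = "none")
  expect_true(low_sample %in% cases3)

  # mismatched pair: empty result with a warning
  fus_alk <- tibble::tibble(sample_id = tumors[1], gene_5prime = "EML4",
                            gene_3prime = "ALK")
  expect_warning(none <- select_cases(fus_alk, co$expression, "RSPO3", tumors),
                 "no fusion calls")
  expect_length(none, 0)
  expect_error(select_cases(co$fusion_calls, co$expression, "NOPE", tumors),
               "NOPE")
})

test_that("control pool is the strict below-median half of non-case tumors", {
  expr <- matrix(c(1, 2, 3, 4), nrow = 1,
                 dimnames = list("RSPO3", sprintf("S%d", 1:4)))
  pool <- build_control_pool(expr, sprintf("S%d", 1:4), character(0), "RSPO3")
  expect_setequal(pool, c("S1", "S2"))  # median 2.5, strict less

  # pool-size law: distinct values, even count -> exactly half
  for (n in c(10, 186 * 2, 372)) {
    vals <- sample(seq_len(n))
    e <- matrix(vals, 1, dimnames = list("RSPO3", sprintf("T%d", seq_len(n))))
    expect_length(build_control_pool(e, colnames(e), character(0), "RSPO3"),
                  n %/% 2)
  }

  tied <- matrix(rep(5, 6), 1, dimnames = list("RSPO3", sprintf("S%d", 1:6)))
  expect_error(build_control_pool(tied, colnames(tied), character(0), "RSPO3"),
               "tied")
  expect_error(build_control_pool(expr, "S1", character(0), "RSPO3"), "fewer")
})

test_that("resample draws are uniform without replacement and reproducible", {
  pool <- sprintf("P%03d", 1:186)
  cases <- sprintf("C%d", 1:7)
  d <- draw_resamples(pool, cases, 100, 50, seed = 3)
  expect_length(d$resample_sets, 100)
  expect_true(all(vapply(d$resample_sets, function(s)
    length(s) == 50 && !anyDuplicated(s) && all(s %in% pool), logical(1))))
  d2 <- draw_resamples(pool, cases, 100, 50, seed = 3)
  expect_identical(d$resample_sets, d2$resample_sets)

  # pool size == control size forces every set to equal the pool
  d3 <- draw_resamples(pool[1:50], cases, 5, 50, seed = 1)
  expect_true(all(vapply(d3$resample_sets, setequal, logical(1), pool[1:50])))
  expect_error(draw_resamples(pool[1:10], cases, 5, 50, seed = 1), "smaller")
  expect_error(draw_resamples(pool, cases[1], 5, 50, seed = 1), "2 case")

  # exchangeability: inclusion frequency of each member ~ control_size/|pool|
  small_pool <- sprintf("Q%02d", 1:20)
  counts <- integer(20)
  for (s in 1:1000) {
    ds <- draw_resamples(small_pool, cases, 1, 5, seed = s)
    counts <- counts + small_pool %in% ds$resample_sets[[1]]
  }
  p <- 5 / 20
  se <- sqrt(p * (1 - p) / 1000)
  expect_true(all(abs(counts / 1000 - p) < 4 * se))

  expect_equal(nrow(tidy(d)), 100 * 50)
  expect_equal(glance(d)$pool_size, 186)
})

test_that("clinical comparison reproduces the printed sex table and the exact test", {
  md <- tibble::tibble(
    sample_id = sprintf("S%03d", 1:193),
    sample_type = "tumor",
    sex = c(rep(c("male", "female"), c(3, 2)), rep(NA, 2),       # 7 cases
            rep(c("male", "female"), c(68, 53)), rep(NA, 65)))   # 186 controls
  cases <- md$sample_id[1:7]
  controls <- md$sample_id[8:193]
  cmp <- clinical_comparison(md, cases, controls, variables = "sex")
  expect_equal(cmp$n_fusion, 5)
  expect_equal(cmp$n_control, 121)
  expect_equal(cmp$p_value, 1.0, tolerance = 1e-12)
  expect_equal(cmp$p_value, fisher_oracle(matrix(c(3, 68, 2, 53), 2)),
               tolerance = 1e-9)

  # identical compositions give p = 1 for any categorical variable
  md2 <- tibble::tibble(sample_id = sprintf("T%02d", 1:40), sample_type = "tumor",
                        msi_status = rep(c("MSS", "MSI-high"), 20))
  cmp2 <- clinical_comparison(md2, md2$sample_id[1:10], md2$sample_id[11:40],
                              variables = "msi_status")
  expect_equal(cmp2$p_value, 1.0)
  expect_error(clinical_comparison(md2, md2$sample_id[1:2], md2$sample_id[3:4],
                                   variables = "stage"), "absent")
})

test_that("Fisher p-values match exact enumeration on random 2xk tables", {
  set.seed(19)
  for (i in 1:20) {
    k <- sample(2:3, 1)
    tab <- matrix(sample(0:8, 2 * k, replace = TRUE), nrow = 2)
    if (any(colSums(tab) == 0) || any(rowSums(tab) == 0)) next
    levels <- LETTERS[seq_len(k)]
    md <- tibble::tibble(
      sample_id = sprintf("X%03d", seq_len(sum(tab))),
      sample_type = "tumor",
      var = c(rep(levels, tab[1, ]), rep(levels, tab[2, ])))
    cases <- md$sample_id[seq_len(sum(tab[1, ]))]
    controls <- setdiff(md$sample_id, cases)
    got <- clinical_comparison(md, cases, controls, variables = "var")$p_value
    expect_equal(got, fisher_oracle(tab), tolerance = 1e-7,
                 label = paste("table", paste(tab, collapse = ",")))
  }
})
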