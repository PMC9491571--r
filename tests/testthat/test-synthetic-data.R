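test_that("cohort counts follow the configuration", {
  co <- simulate_cohort(sim_config(
    n_genes = 1000, n_tumor = 379, n_normal = 53, n_metastasis = 1,
    n_cases = 7, module_sizes = 50, module_rhos = 0.6, seed = 1))
  expect_equal(dim(co$expression), c(1000, 433))
  expect_equal(nrow(co$metadata), 433)
  expect_equal(sum(co$metadata$sample_type == "tumor"), 379)
  expect_equal(sum(co$metadata$sample_type == "normal"), 53)
  expect_equal(sum(co$metadata$sample_type == "metastasis"), 1)
  expect_equal(nrow(co$fusion_calls), 7)
  expect_equal(sum(!is.na(co$truth$module)), 50)
  expect_true(all(co$fusion_calls$sample_id %in%
                    co$metadata$sample_id[co$metadata$sample_type == "tumor"]))
  expect_true(all(co$expression >= 0))
})

test_that("a rho = 0 module is uncorrelated with the reference on the log scale", {
  co <- simulate_cohort(sim_config(
    n_genes = 300, n_tumor = 379, n_normal = 0, n_metastasis = 0, n_cases = 7,
    module_sizes = 100, module_rhos = 0, zero_gene_frac = 0, seed = 42))
  mod <- which(!is.na(co$truth$module))
  lx <- log(co$expression)
  r <- apply(lx[mod, ], 1, function(g) cor(g, lx["RSPO3", ]))
  # Fisher z: at n = 379, |r| < 0.1 has probability ~0.947 per gene under
  # rho = 0 (2*pnorm(0.1*sqrt(376)) - 1); with 100 genes, >= 87 successes
  # has probability > 0.99
  expect_gte(mean(abs(r) < 0.1), 0.87)
})

test_that("case elevation of the reference gene matches the configured shift", {
  cfg <- sim_config(n_genes = 200, n_tumor = 200, n_normal = 0,
                    n_metastasis = 0, n_cases = 7, case_shift = 3,
                    module_sizes = 10, module_rhos = 0.5, seed = 9)
  co <- simulate_cohort(cfg)
  cases <- co$fusion_calls$sample_id
  controls <- setdiff(colnames(co$expression), cases)
  diff <- mean(log(co$expression["RSPO3", cases])) -
    mean(log(co$expression["RSPO3", controls]))
  se <- cfg$lognormal_sigma * sqrt(1 / 7 + 1 / length(controls))
  expect_lt(abs(diff - 3), 3 * se)
  # every case strictly above the tumor-wide median (elevation guarantee)
  expect_true(all(co$expression["RSPO3", cases] >
                    median(co$expression["RSPO3", ])))
})

test_that("module genes hit their latent target correlation and zero genes are flat", {
  co <- small_cohort(seed = 3)
  mod <- which(!is.na(co$truth$module))
  controls <- setdiff(colnames(co$expression), co$fusion_calls$sample_id)
  lx <- log(pmax(co$expression[, controls], .Machine$double.xmin))
  r <- apply(lx[mod, ], 1, function(g) cor(g, lx["RSPO3", controls]))
  # among non-case samples the latent correlation is rho = 0.6
  expect_lt(abs(mean(r) - 0.6), 0.1)
  zeros <- co$truth$gene_id[co$truth$is_zero]
  expect_gte(length(zeros), 1)
  expect_true(all(co$expression[zeros, ] == 0))
})

test_that("generation is reproducible given the seed and config is validated", {
  cfg <- sim_config(n_genes = 150, n_tumor = 40, n_normal = 2,
                    n_metastasis = 0, n_cases = 3, module_sizes = 10,
                    module_rhos = 0.4, seed = 11)
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co1$expression, co2$expression)
  expect_identical(co1$metadata, co2$metadata)
  expect_identical(co1$fusion_calls, co2$fusion_calls)
  expect_error(sim_config(n_cases = 50, n_tumor = 40), "n_cases")
  expect_error(sim_config(module_sizes = 10, module_rhos = 1.2), "module_rho")
  expect_error(sim_config(n_genes = 20, module_sizes = 50, module_rhos = 0.5),
               "exceed")
})

test_that("pathway fixture plants enrichment only when asked", {
  genes <- sprintf("G%04d", 1:400)
  planted <- genes[1:40]
  # enrichment_factor 1: planted inclusion within 2 binomial SE of background
  db1 <- simulate_pathway_db(n_pathways = 40, genes = genes, planted = planted,
                             enrichment_factor = 1, background_rate = 0.1,
                             seed = 2)
  inc <- function(db, gs) mean(vapply(db$pathways$genes,
                                      function(g) mean(gs %in% g), numeric(1)))
  p_pl <- inc(db1, planted); p_bg <- inc(db1, setdiff(genes, planted))
  se <- 2 * sqrt(0.1 * 0.9 / (40 * 40))
  expect_lt(abs(p_pl - p_bg), 2 * se + 0.02)
  expect_false(any(db1$truth$enriched))
  # no planted genes: nothing flagged enriched
  db0 <- simulate_pathway_db(n_pathways = 12, genes = genes,
                             planted = character(), seed = 3)
  expect_false(any(db0$truth$enriched))
  # requested meta groups are delivered exactly
  db2 <- simulate_pathway_db(n_pathways = 50, genes = genes, planted = planted,
                             enrichment_factor = 5, n_meta = 10, seed = 4)
  expect_equal(length(unique(db2$meta_map$meta)), 10)
  expect_setequal(db2$meta_map$pathway_id, db2$pathways$pathway_id)
  expect_true(all(lengths(db2$pathways$genes) > 0))
})

test_that("drug knowledgebase fixture honors its guarantees and determinism", {
  genes <- c("ALK", "TP53", "MYC", "KRAS", "JUN")
  kb1 <- simulate_drug_kb(genes, seed = 5)
  alk_rows <- kb1$civic[kb1$civic$gene == "ALK" &
                          kb1$civic$interaction == "inhibits", ]
  expect_true(any(alk_rows$evidence_tier == "A" &
                    grepl("crizotinib", alk_rows$drugs)))
  expect_true(any(kb1$civic$interaction == "activates" &
                    kb1$civic$gene_role == "tumor_suppressor"))
  expect_true(all(kb1$oncokb$evidence_tier %in% as.character(1:4)))
  # byte-identical files from the same seed
  kb2 <- simulate_drug_kb(genes, seed = 5)
  f1 <- tempfile(); f2 <- tempfile()
  write_drug_kb(kb1$civic, f1, "civic")
  write_drug_kb(kb2$civic, f2, "civic")
  expect_identical(readLines(f1), readLines(f2))
  # the emitted dialects round-trip through the package readers
  ev <- read_drug_kb(f1, "civic")
  expect_true(all(ev$tier %in% c("A", "B", "C", "D", "E")))
  fo <- tempfile()
  write_drug_kb(kb1$oncokb, fo, "oncokb")
  expect_s3_class(read_drug_kb(fo, "oncokb"), "tbl_df")
})
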