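pw_db <- function(...) {
  sets <- list(...)
  tibble::tibble(pathway_id = names(sets), source = "fix", genes = unname(sets))
}

test_that("hypergeometric ORA matches closed cases and the enumeration oracle", {
  uni <- sprintf("g%02d", 1:10)
  db <- pw_db(PW1 = uni[1:4])
  # no overlap: P(X >= 0) = 1
  res0 <- ora_hypergeometric(uni[5:6], db, uni)
  expect_equal(res0$p_value, 1)
  # N=10, K=4, n=5, k=4 -> 6/252
  res <- ora_hypergeometric(c(uni[1:4], uni[10]), db, uni)
  expect_equal(res$k, 4)
  expect_equal(res$p_value, 6 / 252, tolerance = 1e-12)
  # query = universe: k = K, p = 1
  res1 <- ora_hypergeometric(uni, db, uni)
  expect_equal(res1$k, res1$K)
  expect_equal(res1$p_value, 1)
  expect_error(ora_hypergeometric(character(0), db, uni), "query")
  expect_error(ora_hypergeometric("zzz", db, uni), "outside")

  # spot-check against exhaustive enumeration of query draws
  set.seed(12)
  for (i in 1:15) {
    N <- sample(5:12, 1); K <- sample(1:(N - 1), 1); n <- sample(1:N, 1)
    u <- sprintf("u%02d", seq_len(N))
    q <- sample(u, n)
    r <- ora_hypergeometric(q, pw_db(P = u[seq_len(K)]), u)
    expect_equal(r$p_value, hyper_oracle(N, K, n, r$k), tolerance = 1e-12)
  }
})

test_that("BH q-values follow the step-up definition", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_fdr(c(0.2, 1.4)), "0, 1")
  set.seed(5)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # step-up monotonicity
  }
})

test_that("meta-pathway collapse takes unions of significant query overlaps", {
  uni <- sprintf("m%02d", 1:30)
  db <- pw_db(P1 = c("A", "B", uni[1:3]), P2 = c("B", "C", uni[4:6]),
              P3 = uni[7:12])
  map <- tibble::tibble(meta = c("WNT", "WNT", "p53"),
                        pathway_id = c("P1", "P2", "P3"))
  records <- tibble::tibble(pathway_id = c("P1", "P2", "P3"),
                            q_value = c(0.01, 0.04, 0.5))
  query <- c("A", "B", "C", uni[7])
  out <- collapse_to_meta(records, map, db, query)
  expect_setequal(out$meta_genes$gene[out$meta_genes$meta == "WNT"],
                  c("A", "B", "C"))
  expect_equal(sum(out$meta_genes$meta == "p53"), 0)  # P3 not significant
  expect_setequal(out$component_genes, c("A", "B", "C"))
  expect_setequal(out$significant, c("P1", "P2"))

  # nothing significant: all meta sets empty
  rec0 <- dplyr::mutate(records, q_value = 0.9)
  out0 <- collapse_to_meta(rec0, map, db, query)
  expect_equal(nrow(out0$meta_genes), 0)
  expect_length(out0$component_genes, 0)
  expect_error(collapse_to_meta(records,
                                tibble::tibble(meta = "X", pathway_id = "NOPE"),
                                db, query), "unknown")

  # a ten-group fixture map yields exactly ten meta rows in the counts
  sim <- simulate_pathway_db(n_pathways = 30, genes = uni,
                             planted = uni[1:5], n_meta = 10, seed = 2)
  rec <- tibble::tibble(pathway_id = sim$pathways$pathway_id, q_value = 0.01)
  out10 <- collapse_to_meta(rec, sim$meta_map, sim$pathways, uni[1:10])
  expect_equal(nrow(out10$meta_counts), 10)
})

test_that("gene annotation counts multiplicity and applies the key-gene conjunction", {
  metas <- sprintf("MP%02d", 1:10)
  meta_genes <- dplyr::bind_rows(
    tibble::tibble(meta = metas[1:9], gene = "JUN"),
    tibble::tibble(meta = metas[1], gene = "EDGE"),
    tibble::tibble(meta = metas[1:3], gene = "RICH"))
  screen <- tibble::tibble(
    gene_id = c("JUN", "EDGE", "RICH"),
    median_abs_r = c(0.45, 0.3, 0.9),
    median_signed_r = c(0.45, 0.3, -0.9),
    direction = c("up", "up", "down"))
  census <- tibble::tibble(gene = c("JUN", "EDGE"),
                           role = c("oncogene", "tumor_suppressor"))
  ann <- annotate_genes(c("JUN", "EDGE", "RICH"), census, screen, meta_genes)
  expect_equal(ann$meta_pathway_count[ann$gene == "JUN"], 9L)
  expect_true(ann$key_gene[ann$gene == "JUN"])
  # |R| = 0.3 exactly fails the strict threshold
  expect_false(ann$key_gene[ann$gene == "EDGE"])
  # strong non-census gene is never key
  expect_false(ann$key_gene[ann$gene == "RICH"])
  expect_false(ann$is_cancer_gene[ann$gene == "RICH"])
})

test_that("planted pathway enrichment is recovered at q < 0.05", {
  hits <- 0
  for (seed in 1:15) {
    # universe and planted-set proportions mirror the default conditions
    # (a ~50-gene module inside a much larger measured universe)
    genes <- sprintf("g%04d", 1:2000)
    planted <- genes[1:50]
    sim <- simulate_pathway_db(n_pathways = 40, genes = genes,
                               planted = planted, enrichment_factor = 5,
                               n_enriched = 5, background_rate = 0.05,
                               seed = seed)
    uni <- annotated_universe(genes, sim$pathways)
    res <- ora_hypergeometric(intersect(planted, uni), sim$pathways, uni)
    sig <- res$pathway_id[res$q_value < 0.05]
    truth <- sim$truth$pathway_id[sim$truth$enriched]
    hits <- hits + mean(truth %in% sig)
  }
  expect_gte(hits / 15, 0.9)
})

test_that("pathway overlap report is symmetric-complete and bounded", {
  db <- pw_db(A = c("x", "y", "z"), B = c("y", "z", "w"), C = "q")
  jac <- pathway_jaccard(db)
  expect_equal(nrow(jac), 3)
  expect_equal(jac$jaccard[jac$pathway_a == "A" & jac$pathway_b == "B"], 0.5)
  expect_true(all(jac$jaccard >= 0 & jac$jaccard <= 1))
})
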