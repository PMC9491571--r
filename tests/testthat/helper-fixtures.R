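# Shared fixtures and independent oracles. Oracles are deliberately naive
# (enumeration / direct definition) and never call the code paths they check.

# A small cohort exercised by most stage tests: 300 genes, 60 tumors + 5
# normals + 1 metastasis, 4 fusion cases, one 30-gene module at rho 0.6.
small_cohort <- function(seed = 7) {
  simulate_cohort(sim_config(
    n_genes = 300, n_tumor = 60, n_normal = 5, n_metastasis = 1, n_cases = 4,
    module_sizes = 30, module_rhos = 0.6, zero_gene_frac = 0.01, seed = seed))
}

small_design <- function(cohort, n_resamples = 50, control_size = 20, seed = 5) {
  tumors <- filter_tumor_samples(cohort$metadata)
  cases <- select_cases(cohort$fusion_calls, cohort$expression, "RSPO3", tumors)
  pool <- build_control_pool(cohort$expression, tumors, cases, "RSPO3")
  draw_resamples(pool, cases, n_resamples, control_size, seed = seed)
}

# --- exact Fisher oracle: enumeration of all 2 x k tables with fixed
# margins, two-sided by probability ordering (tables no more probable than
# the observed one). `tab`: 2 x k matrix.
fisher_oracle <- function(tab) {
  stopifnot(nrow(tab) == 2)
  col_tot <- colSums(tab)
  row1 <- sum(tab[1, ])
  k <- ncol(tab)
  log_prob <- function(x1) {
    # x1: first-row counts; multivariate hypergeometric mass
    sum(lchoose(col_tot, x1)) - lchoose(sum(col_tot), row1)
  }
  # enumerate all first rows with sum row1, 0 <= x1_j <= col_tot[j]
  grids <- lapply(col_tot, function(m) 0:m)
  combos <- expand.grid(grids)
  combos <- combos[rowSums(combos) == row1, , drop = FALSE]
  lp <- apply(combos, 1, log_prob)
  lp_obs <- log_prob(tab[1, ])
  sum(exp(lp[lp <= lp_obs + 1e-7]))
}

# --- exact upper-tail hypergeometric oracle via enumeration of all query
# draws of size n from a universe of size N containing a K-gene pathway.
hyper_oracle <- function(N, K, n, k) {
  if (k <= 0) return(1)
  draws <- utils::combn(N, n)
  in_pathway <- draws <= K  # wlog pathway = first K elements
  mean(colSums(in_pathway) >= k)
}

# --- independent BH step-up implementation from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Tiny drug-evidence fixture around ALK (up-regulated oncogene) and a
# down-regulated tumor suppressor.
alk_fixture <- function() {
  annotations <- tibble::tibble(
    gene = c("ALK", "TP53", "GNAQ"),
    is_cancer_gene = TRUE,
    role = c("oncogene", "tumor_suppressor", "oncogene"),
    meta_pathway_count = c(2L, 5L, 1L),
    median_abs_r = c(0.44, 0.33, 0.31),
    median_signed_r = c(0.44, -0.33, 0.31),
    direction = c("up", "down", "up"),
    key_gene = c(TRUE, TRUE, FALSE))
  civic <- tibble::tibble(
    gene = c("ALK", "ALK", "ALK", "TP53"),
    drug = c("crizotinib", "alectinib", "ceritinib", "p53activator"),
    interaction = c("inhibits", "inhibits", "inhibits", "activates"),
    tier = c("A", "A", "A", "C"),
    gene_role = c("oncogene", "oncogene", "oncogene", "tumor_suppressor"),
    disease = "colorectal cancer", source = "civic")
  oncokb <- tibble::tibble(
    gene = "ALK", drug = "lorlatinib", interaction = "inhibits", tier = "1",
    gene_role = "oncogene", disease = "colorectal cancer", source = "oncokb")
  list(annotations = annotations, civic = civic, oncokb = oncokb)
}
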