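# Synthetic TCGA-like cohort generator: log-normal expression marginals,
# planted correlation modules on the latent log scale, fusion-positive cases
# with an elevated reference gene, and Table-1-style clinical metadata.

#' Simulation configuration for a synthetic fusion cohort
#'
#' Defines the shape and statistical structure of a synthetic bulk-expression
#' cohort emulating a TCGA colorectal collection with a small set of
#' fusion-positive cases. Defaults reproduce the scale of the motivating
#' dataset: 20,531 genes over 433 samples (379 primary tumors, 53 normals,
#' 1 metastasis), with 7 fusion-positive cases whose reference gene
#' (RSPO3 by default) is elevated on the log scale.
#'
#' Expression marginals are log-normal: `exp(mu + sigma * Z)` with `Z`
#' standard normal, a heavy-tailed non-negative stand-in for RSEM-style
#' normalized counts. Gene modules are planted on the latent (log) scale:
#' a module gene with target correlation `rho` uses
#' `Z_g = rho * Z_ref + sqrt(1 - rho^2) * eps`, so the realized log-scale
#' Pearson correlation with the reference gene approaches `rho` as the sample
#' size grows; the raw-scale correlation is attenuated relative to `rho`.
#'
#' @param n_genes Number of genes (includes the reference gene).
#' @param n_tumor,n_normal,n_metastasis Sample counts by type.
#' @param n_cases Number of fusion-positive tumor samples (< `n_tumor`).
#' @param reference_gene Identifier of the reference gene.
#' @param fusion_partner 5'-partner gene symbol recorded in fusion calls (also
#'   included as an ordinary background gene in the matrix).
#' @param case_shift Additive elevation of the reference gene in cases on the
#'   natural-log scale (default 3, roughly a 20-fold elevation).
#' @param module_sizes,module_rhos Integer sizes and latent target Pearson
#'   correlations (each in (-1, 1)) of the planted modules, one rho per module.
#' @param lognormal_mu,lognormal_sigma Marginal log-scale mean and SD shared
#'   by all genes.
#' @param zero_gene_frac Fraction of genes set identically to zero, to
#'   exercise degenerate-variance handling downstream.
#' @param clinical_proportions Named list of categorical distributions for the
#'   clinical covariates; see [default_clinical_proportions()].
#' @param clinical_missing_frac Fraction of missing values injected into the
#'   non-mutation clinical covariates.
#' @param seed Integer seed; the generator is fully reproducible given it.
#' @return A validated `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 200, seed = 1)
sim_config <- function(n_genes = 20531L,
                       n_tumor = 379L,
                       n_normal = 53L,
                       n_metastasis = 1L,
                       n_cases = 7L,
                       reference_gene = "RSPO3",
                       fusion_partner = "PTPRK",
                       case_shift = 3,
                       module_sizes = 50L,
                       module_rhos = 0.6,
                       lognormal_mu = 6,
                       lognormal_sigma = 1,
                       zero_gene_frac = 0.005,
                       clinical_proportions = default_clinical_proportions(),
                       clinical_missing_frac = 0.35,
                       seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes", min = 2L)
  n_tumor <- check_count(n_tumor, "n_tumor", min = 1L)
  n_normal <- check_count(n_normal, "n_normal")
  n_metastasis <- check_count(n_metastasis, "n_metastasis")
  n_cases <- check_count(n_cases, "n_cases")
  if (n_cases >= n_tumor) stop_fs("n_cases (%d) must be < n_tumor (%d)", n_cases, n_tumor)
  module_sizes <- vapply(module_sizes, check_count, integer(1), name = "module_sizes", min = 1L)
  if (length(module_sizes) != length(module_rhos)) {
    stop_fs("module_sizes and module_rhos must have equal length")
  }
  if (any(abs(module_rhos) >= 1)) stop_fs("each |module_rho| must be < 1")
  # reference + fusion partner + modules must fit
  if (sum(module_sizes) + 2L > n_genes) stop_fs("module sizes exceed n_genes")
  check_prob(zero_gene_frac, "zero_gene_frac")
  check_prob(clinical_missing_frac, "clinical_missing_frac")
  if (lognormal_sigma <= 0) stop_fs("lognormal_sigma must be > 0")
  structure(
    list(n_genes = n_genes, n_tumor = n_tumor, n_normal = n_normal,
         n_metastasis = n_metastasis, n_cases = n_cases,
         reference_gene = reference_gene, fusion_partner = fusion_partner,
         case_shift = case_shift,
         module_sizes = as.integer(module_sizes),
         module_rhos = as.numeric(module_rhos),
         lognormal_mu = lognormal_mu, lognormal_sigma = lognormal_sigma,
         zero_gene_frac = zero_gene_frac,
         clinical_proportions = clinical_proportions,
         clinical_missing_frac = clinical_missing_frac,
         seed = check_count(seed, "seed")),
    class = "sim_config")
}

#' Default clinical covariate distributions
#'
#' Category weights for the simulated clinical table, taken from the observed
#' control-group composition of the motivating fusion-negative colorectal
#' cohort (counts, normalized internally): sex 68M/53F, vital status
#' 101 alive/20 dead, stage 20/48/33/15 (I-IV), MSI 18 high/19 low/84 MSS,
#' histology 113 adenocarcinoma/7 mucinous; mutation prevalences TP53 113/186,
#' KRAS 80/186, PIK3CA 50/186, PTEN 15/186, BRAF 23/186.
#'
#' @return Named list of named numeric weight vectors plus `mutation_rates`.
#' @export
default_clinical_proportions <- function() {
  list(
    sex = c(male = 68, female = 53),
    vital_status = c(alive = 101, dead = 20),
    stage = c("I" = 20, "II" = 48, "III" = 33, "IV" = 15),
    msi_status = c("MSI-high" = 18, "MSI-low" = 19, "MSS" = 84),
    histology = c("adenocarcinoma" = 113, "mucinous adenocarcinoma" = 7),
    age_range = c(31, 90),
    mutation_rates = c(TP53 = 113 / 186, KRAS = 80 / 186, PIK3CA = 50 / 186,
                       PTEN = 15 / 186, BRAF = 23 / 186)
  )
}

#' Generate a synthetic fusion cohort
#'
#' Draws an expression matrix, clinical metadata, fusion calls and a
#' per-gene truth table under a [sim_config()]. Fusion-positive cases are
#' `n_cases` tumor samples drawn at random; the reference gene's latent
#' score is shifted in cases by `case_shift / lognormal_sigma` (so its mean
#' log expression rises by about `case_shift`) and redrawn from the shifted
#' law until strictly above the tumor-wide median, so the cases always
#' satisfy the downstream elevation rule. Because the shift is applied on
#' the latent scale before module genes are drawn, planted genes inherit a
#' case elevation of about `rho * case_shift` on the log scale — the
#' downstream response a fusion-driven reference gene induces in genes
#' genuinely correlated with it.
#'
#' @param config A [sim_config()] object.
#' @return A `synthetic_cohort` list with elements `expression` (numeric
#'   genes x samples matrix), `metadata` (tibble), `fusion_calls` (tibble),
#'   `truth` (tibble: gene_id, module, target_rho, is_zero) and `config`.
#' @export
#' @examples
#' co <- simulate_cohort(sim_config(n_genes = 300, n_tumor = 60, n_normal = 5,
#'                                  n_metastasis = 0, n_cases = 4, seed = 7))
#' dim(co$expression)
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) stop_fs("config must be a sim_config")
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  n_samples <- config$n_tumor + config$n_normal + config$n_metastasis
  sample_ids <- c(sprintf("T%04d", seq_len(config$n_tumor)),
                  if (config$n_normal > 0) sprintf("N%04d", seq_len(config$n_normal)),
                  if (config$n_metastasis > 0) sprintf("M%04d", seq_len(config$n_metastasis)))
  sample_type <- rep(c("tumor", "normal", "metastasis"),
                     c(config$n_tumor, config$n_normal, config$n_metastasis))

  n_other <- config$n_genes - 2L  # minus reference and fusion partner
  gene_ids <- c(config$reference_gene, config$fusion_partner,
                sprintf("G%05d", seq_len(n_other)))

  # planted module membership (latent-scale rho), disjoint, excluding the
  # reference and the fusion partner
  module <- rep(NA_integer_, config$n_genes)
  target_rho <- rep(NA_real_, config$n_genes)
  pos <- 3L
  for (m in seq_along(config$module_sizes)) {
    idx <- seq.int(pos, length.out = config$module_sizes[m])
    module[idx] <- m
    target_rho[idx] <- config$module_rhos[m]
    pos <- pos + config$module_sizes[m]
  }

  # all-zero genes drawn among unplanted background genes
  bg <- which(is.na(module))[-(1:2)]
  n_zero <- min(length(bg), round(config$zero_gene_frac * config$n_genes))
  zero_idx <- if (n_zero > 0) sample(bg, n_zero) else integer(0)

  # fusion-positive cases: the reference gene's latent score is shifted by
  # case_shift / sigma (so its log expression rises by ~case_shift), with
  # rejection resampling so every case ends strictly above the tumor-wide
  # median. The shift is applied on the LATENT scale before module genes are
  # drawn, so planted genes respond to the fusion in proportion to their
  # rho — emulating downstream genes of the fusion-elevated reference.
  tumor_idx <- which(sample_type == "tumor")
  case_idx <- sort(sample(tumor_idx, config$n_cases))
  shift <- config$case_shift / config$lognormal_sigma
  z_ref <- rnorm(n_samples)
  z_ref[case_idx] <- z_ref[case_idx] + shift
  repeat {
    thr <- median(z_ref[tumor_idx])
    low <- case_idx[z_ref[case_idx] <= thr]
    if (length(low) == 0) break
    z_ref[low] <- rnorm(length(low)) + shift
  }
  z <- matrix(rnorm(config$n_genes * n_samples), config$n_genes, n_samples)
  z[1, ] <- z_ref
  in_mod <- !is.na(module)
  if (any(in_mod)) {
    rho <- target_rho[in_mod]
    z[in_mod, ] <- rho * matrix(z_ref, sum(in_mod), n_samples, byrow = TRUE) +
      sqrt(1 - rho^2) * z[in_mod, , drop = FALSE]
  }
  expr <- exp(config$lognormal_mu + config$lognormal_sigma * z)
  if (n_zero > 0) expr[zero_idx, ] <- 0
  dimnames(expr) <- list(gene_ids, sample_ids)

  metadata <- simulate_metadata(sample_ids, sample_type, config)
  fusion_calls <- tibble(sample_id = sample_ids[case_idx],
                         gene_5prime = config$fusion_partner,
                         gene_3prime = config$reference_gene)
  truth <- tibble(gene_id = gene_ids, module = module, target_rho = target_rho,
                  is_zero = seq_len(config$n_genes) %in% zero_idx)

  structure(list(expression = expr, metadata = metadata,
                 fusion_calls = fusion_calls, truth = truth, config = config),
            class = "synthetic_cohort")
}

simulate_metadata <- function(sample_ids, sample_type, config) {
  p <- config$clinical_proportions
  n <- length(sample_ids)
  draw_cat <- function(w) {
    x <- sample(names(w), n, replace = TRUE, prob = w / sum(w))
    x[runif(n) < config$clinical_missing_frac] <- NA_character_
    x
  }
  mut <- p$mutation_rates
  md <- tibble(
    sample_id = sample_ids,
    sample_type = sample_type,
    age = round(runif(n, p$age_range[1], p$age_range[2])),
    sex = draw_cat(p$sex),
    vital_status = draw_cat(p$vital_status),
    stage = draw_cat(p$stage),
    msi_status = draw_cat(p$msi_status),
    histology = draw_cat(p$histology)
  )
  for (g in names(mut)) {
    md[[paste0("mut_", g)]] <- runif(n) < mut[[g]]
  }
  md
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$expression), " genes x ",
      ncol(x$expression), " samples; ", nrow(x$fusion_calls),
      " fusion-positive cases; ", sum(!is.na(x$truth$module)),
      " planted module genes\n", sep = "")
  invisible(x)
}

# Evaluate code under a temporary RNG state; restores the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
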