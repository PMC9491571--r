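# Fixture pathway databases, meta-pathway maps, drug knowledgebases and
# cancer-gene lists with known ground truth, for exercising the enrichment
# and drug-network stages without external downloads.

META_PATHWAY_NAMES <- c("Apoptosis", "Direct p53", "EGFR", "ErbB", "JAK-STAT",
                        "Tyrosine kinases", "Pathways in cancer", "SCF-KIT",
                        "VEGFR", "WNT")

#' Generate a synthetic pathway database with planted enrichment
#'
#' Builds a GMT-style pathway collection over a gene universe in which a
#' designated subset of pathways over-includes a planted gene list. Every
#' gene enters a pathway independently at a background rate; in the
#' designated "enriched" pathways, planted genes enter at
#' `enrichment_factor` times that rate (capped at 1). Pathways are grouped
#' into named meta-pathways, emulating the curated collapse of source-database
#' pathways into cancer-related groups.
#'
#' @param n_pathways Number of pathways.
#' @param genes Character vector, the gene universe.
#' @param planted Character vector of planted genes (subset of `genes`).
#' @param enrichment_factor Multiplier (>= 0) on the planted genes' inclusion
#'   rate in enriched pathways; 1 means no enrichment.
#' @param n_enriched Number of pathways that over-include the planted genes.
#' @param n_meta Number of meta-pathway groups (default 10; the default group
#'   names follow common cancer signaling themes).
#' @param background_rate Per-gene background inclusion probability.
#' @param seed Integer seed.
#' @return List with `pathways` (tibble: pathway_id, source, genes list-column),
#'   `meta_map` (tibble: meta, pathway_id) and `truth` (tibble: pathway_id,
#'   enriched flag).
#' @export
simulate_pathway_db <- function(n_pathways = 50L, genes, planted = character(),
                                enrichment_factor = 5, n_enriched = 10L,
                                n_meta = 10L, background_rate = 0.05,
                                seed = 1L) {
  n_pathways <- check_count(n_pathways, "n_pathways", min = 1L)
  n_meta <- check_count(n_meta, "n_meta", min = 1L)
  if (length(genes) == 0) stop_fs("gene universe must be non-empty")
  if (!all(planted %in% genes)) stop_fs("planted genes must be a subset of the universe")
  if (enrichment_factor < 0) stop_fs("enrichment_factor must be >= 0")
  n_enriched <- min(check_count(n_enriched, "n_enriched"), n_pathways)
  with_seed(seed, {
    ids <- sprintf("PW%03d", seq_len(n_pathways))
    sources <- sample(c("KEGG", "Reactome", "WikiPathways", "PID", "INOH", "NetPath"),
                      n_pathways, replace = TRUE)
    enriched <- logical(n_pathways)
    if (length(planted) > 0 && enrichment_factor != 1) {
      enriched[seq_len(n_enriched)] <- TRUE
    }
    planted_rate <- min(1, background_rate * enrichment_factor)
    is_planted <- genes %in% planted
    sets <- lapply(seq_len(n_pathways), function(i) {
      rate <- rep(background_rate, length(genes))
      if (length(planted) > 0 && i <= n_enriched) rate[is_planted] <- planted_rate
      members <- genes[runif(length(genes)) < rate]
      # gene sets must be non-empty
      if (length(members) == 0) members <- sample(genes, 1)
      members
    })
    meta_names <- if (n_meta <= length(META_PATHWAY_NAMES)) {
      META_PATHWAY_NAMES[seq_len(n_meta)]
    } else {
      sprintf("META%02d", seq_len(n_meta))
    }
    meta_map <- tibble(meta = meta_names[((seq_len(n_pathways) - 1L) %% n_meta) + 1L],
                       pathway_id = ids)
    list(
      pathways = tibble(pathway_id = ids, source = sources, genes = sets),
      meta_map = dplyr::arrange(meta_map, .data$meta, .data$pathway_id),
      truth = tibble(pathway_id = ids, enriched = enriched)
    )
  })
}

#' Generate synthetic drug knowledgebases and a cancer-gene list
#'
#' Emits fixture evidence tables in the CIViC-like and OncoKB-like dialects
#' the package reads, plus a census-style cancer-gene list with
#' oncogene/tumor-suppressor roles. The tables always contain at least one
#' oncogene with a top-tier inhibitor and one tumor suppressor with an
#' activator; if `"ALK"` is among `genes` it receives crizotinib, alectinib
#' and ceritinib inhibitor rows at CIViC evidence level A and OncoKB level 1.
#'
#' @param genes Non-empty character vector of genes to annotate.
#' @param n_civic_rows,n_oncokb_rows Extra randomized evidence rows.
#' @param seed Integer seed.
#' @return List with tibbles `civic`, `oncokb` (gene, drugs, interaction,
#'   evidence_tier, gene_role, disease) and `census` (gene, role).
#' @export
simulate_drug_kb <- function(genes, n_civic_rows = 30L, n_oncokb_rows = 10L,
                             seed = 1L) {
  if (length(genes) == 0) stop_fs("gene list must be non-empty")
  genes <- unique(genes)
  with_seed(seed, {
    roles <- sample(c("oncogene", "tumor_suppressor", "both", "unknown"),
                    length(genes), replace = TRUE,
                    prob = c(0.35, 0.3, 0.05, 0.3))
    names(roles) <- genes
    # guarantees: one oncogene/inhibitor at top tier, one TSG/activator
    anchor_og <- if ("ALK" %in% genes) "ALK" else genes[1]
    roles[anchor_og] <- "oncogene"
    anchor_ts <- genes[genes != anchor_og][1]
    if (!is.na(anchor_ts)) roles[anchor_ts] <- "tumor_suppressor"

    civic <- tibble(
      gene = sample(genes, n_civic_rows, replace = TRUE),
      drugs = sprintf("drug%03d", sample(200, n_civic_rows, replace = TRUE)),
      interaction = sample(c("inhibits", "activates", "other"), n_civic_rows,
                           replace = TRUE, prob = c(0.6, 0.2, 0.2)),
      evidence_tier = sample(c("A", "B", "C", "D", "E"), n_civic_rows,
                             replace = TRUE),
      disease = "colorectal cancer"
    )
    civic <- dplyr::bind_rows(
      tibble(gene = anchor_og,
             drugs = if (anchor_og == "ALK") "crizotinib,alectinib,ceritinib"
                     else "inhibitorX",
             interaction = "inhibits", evidence_tier = "A",
             disease = "colorectal cancer"),
      if (!is.na(anchor_ts)) tibble(gene = anchor_ts, drugs = "activatorY",
                                    interaction = "activates",
                                    evidence_tier = "B",
                                    disease = "colorectal cancer"),
      civic)
    oncokb <- tibble(
      gene = sample(genes, n_oncokb_rows, replace = TRUE),
      drugs = sprintf("drug%03d", sample(200, n_oncokb_rows, replace = TRUE)),
      interaction = sample(c("inhibits", "activates", "other"), n_oncokb_rows,
                           replace = TRUE, prob = c(0.7, 0.15, 0.15)),
      evidence_tier = as.character(sample(1:4, n_oncokb_rows, replace = TRUE)),
      disease = "colorectal cancer"
    )
    oncokb <- dplyr::bind_rows(
      tibble(gene = anchor_og,
             drugs = if (anchor_og == "ALK") "crizotinib,alectinib,ceritinib"
                     else "inhibitorX",
             interaction = "inhibits", evidence_tier = "1",
             disease = "colorectal cancer"),
      oncokb)
    civic$gene_role <- unname(roles[civic$gene])
    oncokb$gene_role <- unname(roles[oncokb$gene])
    cols <- c("gene", "drugs", "interaction", "evidence_tier", "gene_role", "disease")
    list(civic = civic[, cols], oncokb = oncokb[, cols],
         census = tibble(gene = genes, role = unname(roles)))
  })
}
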