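# Over-representation analysis of the selected gene list, FDR control,
# collapse of significant pathways into curated meta-pathways, cancer-gene
# annotation, pathway-multiplicity counting, and key-gene selection.

#' Hypergeometric over-representation analysis
#'
#' One-sided upper-tail hypergeometric test per pathway: with a universe of
#' `N` genes, a pathway covering `K` of them and a query of `n` genes
#' overlapping the pathway in `k`, the enrichment p-value is
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. Pathways are intersected
#' with the universe first; pathways with no universe gene are skipped.
#' Benjamini-Hochberg q-values are attached.
#'
#' @param query Character vector of query genes (must lie in `universe`).
#' @param db Pathway tibble (`pathway_id`, `source`, `genes` list-column).
#' @param universe Character vector, the background gene universe. The
#'   conventional ORA background is the annotated universe — measured genes
#'   appearing in at least one pathway; see [annotated_universe()].
#' @return Tibble: `pathway_id`, `k`, `K`, `n`, `N`, `p_value`, `q_value`.
#' @export
ora_hypergeometric <- function(query, db, universe) {
  query <- unique(query); universe <- unique(universe)
  if (length(universe) == 0) stop_fs("empty universe")
  if (length(query) == 0) stop_fs("empty query")
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    stop_fs("query gene(s) outside the universe: %s",
            paste(head(outside, 5), collapse = ", "))
  }
  n <- length(query); N <- length(universe)
  res <- purrr::map_dfr(seq_len(nrow(db)), function(i) {
    pw <- intersect(db$genes[[i]], universe)
    K <- length(pw)
    if (K == 0) return(NULL)
    k <- length(intersect(pw, query))
    tibble(pathway_id = db$pathway_id[i], k = k, K = K, n = n, N = N,
           p_value = phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  })
  if (nrow(res) == 0) stop_fs("no pathway overlaps the universe")
  res$q_value <- bh_fdr(res$p_value)
  res
}

#' Genes measured and annotated in at least one pathway
#'
#' The default ORA background: expression-matrix genes appearing in at least
#' one pathway of the database.
#'
#' @param expr Expression matrix (or character vector of measured genes).
#' @param db Pathway tibble.
#' @return Character vector.
#' @export
annotated_universe <- function(expr, db) {
  measured <- if (is.matrix(expr)) rownames(expr) else expr
  intersect(measured, unique(unlist(db$genes)))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: on the sorted p-value scale,
#' `q(i) = min_{j >= i} p(j) * m / j`, mapped back to input order and capped
#' at 1.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop_fs("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Collapse significant pathways into meta-pathways
#'
#' Keeps pathways with `q < q_threshold` and, for each meta-pathway group,
#' takes the union of (pathway genes intersected with the query) over its
#' significant member pathways. Also emits the global union of component
#' genes across all meta-pathways.
#'
#' @param records ORA results from [ora_hypergeometric()].
#' @param map Meta-pathway map tibble (`meta`, `pathway_id`); every mapped
#'   pathway must exist in `db`.
#' @param db Pathway tibble.
#' @param query The query gene set used for the ORA.
#' @param q_threshold Significance threshold on the q-value (default 0.05;
#'   0.2 is a documented alternative profile).
#' @return List: `meta_genes` (long tibble `meta`, `gene`), `meta_counts`
#'   (tibble `meta`, `n_pathways_significant`, `n_genes`), `component_genes`
#'   (character vector), `significant` (pathway IDs kept).
#' @export
collapse_to_meta <- function(records, map, db, query, q_threshold = 0.05) {
  check_prob(q_threshold, "q_threshold")
  unknown <- setdiff(map$pathway_id, db$pathway_id)
  if (length(unknown) > 0) {
    stop_fs("meta map references unknown pathway(s): %s",
            paste(head(unknown, 5), collapse = ", "))
  }
  sig <- records$pathway_id[records$q_value < q_threshold]
  gene_sets <- setNames(db$genes, db$pathway_id)
  metas <- unique(map$meta)
  meta_genes <- purrr::map_dfr(metas, function(m) {
    pws <- intersect(map$pathway_id[map$meta == m], sig)
    genes <- sort(unique(intersect(unlist(gene_sets[pws]), query)))
    if (length(genes) == 0) return(tibble(meta = character(), gene = character()))
    tibble(meta = m, gene = genes)
  })
  meta_counts <- tibble(meta = metas) |>
    mutate(
      n_pathways_significant = vapply(
        metas, function(m) length(intersect(map$pathway_id[map$meta == m], sig)),
        integer(1)),
      n_genes = vapply(
        metas, function(m) sum(meta_genes$meta == m), integer(1)))
  list(meta_genes = meta_genes, meta_counts = meta_counts,
       component_genes = sort(unique(meta_genes$gene)), significant = sig)
}

#' Annotate component genes with cancer-gene status and key-gene calls
#'
#' Flags census membership, counts the meta-pathways containing each gene
#' (pathway multiplicity), and calls key genes by the conjunction: annotated
#' cancer gene AND median |R| strictly above `key_r_threshold` AND present in
#' at least `key_min_pathways` meta-pathways.
#'
#' @param component_genes Character vector (the meta-pathway gene union).
#' @param census Cancer-gene tibble (`gene`, `role`).
#' @param screen A `screen_result` tibble.
#' @param meta_genes Long tibble (`meta`, `gene`) from [collapse_to_meta()].
#' @param key_r_threshold Median-|R| threshold for key genes (default 0.3).
#' @param key_min_pathways Minimum meta-pathway multiplicity (default 2).
#' @return Tibble: `gene`, `is_cancer_gene`, `role`, `meta_pathway_count`,
#'   `median_abs_r`, `median_signed_r`, `direction`, `key_gene`; ordered by
#'   decreasing median |R|.
#' @export
annotate_genes <- function(component_genes, census, screen, meta_genes,
                           key_r_threshold = 0.3, key_min_pathways = 2L) {
  check_prob(key_r_threshold, "key_r_threshold")
  key_min_pathways <- check_count(key_min_pathways, "key_min_pathways")
  counts <- meta_genes |>
    filter(.data$gene %in% component_genes) |>
    dplyr::count(.data$gene, name = "meta_pathway_count")
  tibble(gene = component_genes) |>
    left_join(counts, by = "gene") |>
    mutate(meta_pathway_count = tidyr::replace_na(.data$meta_pathway_count, 0L)) |>
    left_join(census |> select(gene = "gene", role = "role"), by = "gene") |>
    mutate(is_cancer_gene = !is.na(.data$role),
           role = dplyr::coalesce(.data$role, "unknown")) |>
    left_join(screen |> select(gene = "gene_id", "median_abs_r",
                               "median_signed_r", "direction"),
              by = "gene") |>
    mutate(key_gene = .data$is_cancer_gene &
             !is.na(.data$median_abs_r) &
             .data$median_abs_r > key_r_threshold &
             .data$meta_pathway_count >= key_min_pathways) |>
    arrange(desc(.data$median_abs_r), .data$gene) |>
    select("gene", "is_cancer_gene", "role", "meta_pathway_count",
           "median_abs_r", "median_signed_r", "direction", "key_gene")
}

#' Pairwise gene-overlap (Jaccard) between pathways
#'
#' Curation aid for building a meta-pathway map: reports the Jaccard index of
#' every pathway pair. No automatic merging is performed — collapsing source
#' pathways into meta-pathways is a curation act consumed as an explicit map.
#'
#' @param db Pathway tibble.
#' @return Tibble: `pathway_a`, `pathway_b`, `jaccard`; decreasing.
#' @export
pathway_jaccard <- function(db) {
  n <- nrow(db)
  if (n < 2) return(tibble(pathway_a = character(), pathway_b = character(),
                           jaccard = numeric()))
  pairs <- utils::combn(n, 2)
  jac <- vapply(seq_len(ncol(pairs)), function(j) {
    a <- db$genes[[pairs[1, j]]]; b <- db$genes[[pairs[2, j]]]
    length(intersect(a, b)) / length(union(a, b))
  }, numeric(1))
  tibble(pathway_a = db$pathway_id[pairs[1, ]],
         pathway_b = db$pathway_id[pairs[2, ]],
         jaccard = jac) |>
    arrange(desc(.data$jaccard))
}

#' Export a colored-gene-list (gene, direction) table
#'
#' Substrate for external pathway-map painting tools: each component gene
#' with its expression direction from the screen.
#'
#' @param annotations Tibble from [annotate_genes()].
#' @param path Output path.
#' @export
write_gene_directions <- function(annotations, path) {
  readr::write_tsv(annotations[, c("gene", "direction")], path, progress = FALSE)
  invisible(path)
}
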