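# Direction-aware actionable-drug matching and the prioritized drug-target
# network: inhibitors for up-regulated oncogenes, activators for
# down-regulated tumor suppressors.

#' Match annotated genes against drug knowledgebases
#'
#' Inner join of the component-gene annotations with CIViC-style and
#' OncoKB-style evidence rows on the gene symbol; evidence from both sources
#' is kept with its provenance. Genes with no evidence in either source are
#' returned as a side report rather than entering the network. Gene roles
#' come from the census annotation; when a knowledgebase row disagrees, the
#' census role wins and the conflict is recorded in the `role_conflict`
#' column.
#'
#' @param annotations Tibble from [annotate_genes()].
#' @param civic,oncokb Evidence tibbles from [read_drug_kb()] (may be empty).
#' @return List: `matched` (evidence rows joined with gene direction, role,
#'   multiplicity) and `unmatched` (character vector of undruggable genes).
#' @export
match_actionable <- function(annotations, civic, oncokb) {
  ev <- bind_rows(civic, oncokb)
  gene_info <- annotations |>
    select("gene", "direction", census_role = "role", "meta_pathway_count")
  matched <- ev |>
    inner_join(gene_info, by = "gene") |>
    mutate(role_conflict = .data$gene_role != "unknown" &
             .data$census_role != "unknown" &
             .data$gene_role != .data$census_role,
           role = dplyr::if_else(.data$census_role != "unknown",
                                 .data$census_role, .data$gene_role)) |>
    select("gene", "drug", "interaction", "tier", "source", "disease",
           "direction", "role", "meta_pathway_count", "role_conflict")
  list(matched = matched,
       unmatched = sort(setdiff(annotations$gene, matched$gene)))
}

#' Prioritize drug-gene relations by the oncogene/suppressor scenario
#'
#' A relation is prioritized exactly when it matches the therapeutic
#' scenario: the drug inhibits an up-regulated oncogene, or the drug
#' activates a down-regulated tumor suppressor. Any other premise triple —
#' including flat direction, unknown or ambiguous role, or an `"other"`
#' interaction — is not prioritized, and the rationale names the failed
#' premise. Vectorized over its arguments.
#'
#' @param interaction `"inhibits"`, `"activates"` or `"other"`.
#' @param direction Gene expression direction: `"up"`, `"down"` or `"flat"`.
#' @param role Gene role: `"oncogene"`, `"tumor_suppressor"`, `"both"` or
#'   `"unknown"`.
#' @return Tibble: `prioritized` (logical), `rationale` (character).
#' @export
prioritize <- function(interaction, direction, role) {
  n <- max(length(interaction), length(direction), length(role))
  interaction <- rep_len(interaction, n)
  direction <- rep_len(direction, n)
  role <- rep_len(role, n)
  hit_og <- interaction == "inhibits" & direction == "up" & role == "oncogene"
  hit_ts <- interaction == "activates" & direction == "down" &
    role == "tumor_suppressor"
  rationale <- dplyr::case_when(
    hit_og ~ "inhibitor of up-regulated oncogene",
    hit_ts ~ "activator of down-regulated tumor suppressor",
    role %in% c("unknown", "both") ~ paste0("gene role ", role, ": scenario premise unmet"),
    direction == "flat" ~ "flat expression direction: scenario premise unmet",
    TRUE ~ sprintf("%s/%s/%s does not match the scenario", interaction,
                   direction, role)
  )
  tibble(prioritized = hit_og | hit_ts, rationale = rationale)
}

#' Build the drug-target network
#'
#' Bipartite drug-gene graph from matched evidence: one node per drug and
#' per gene, one edge per (drug, gene, source) evidence tuple, each edge
#' carrying its evidence tier and the scenario-rule prioritization. Per-drug
#' and per-gene best tiers use the documented orderings (CIViC A > B > C >
#' D > E; OncoKB 1 > 2 > 3 > 4), kept separate per source. Node and edge
#' order in the object and its exports is deterministic.
#'
#' @param matched Matched-evidence tibble from [match_actionable()].
#' @return A `drug_target_network`: list with `nodes` and `edges` tibbles.
#' @export
build_network <- function(matched) {
  if (nrow(matched) == 0) {
    nodes <- tibble(node = character(), type = character(),
                    direction = character(), role = character(),
                    meta_pathway_count = integer(),
                    best_tier_civic = character(),
                    best_tier_oncokb = character())
    edges <- tibble(drug = character(), gene = character(),
                    interaction = character(), tier = character(),
                    source = character(), prioritized = logical(),
                    rationale = character())
    return(new_drug_target_network(nodes, edges))
  }
  pr <- prioritize(matched$interaction, matched$direction, matched$role)
  edges <- matched |>
    mutate(prioritized = pr$prioritized, rationale = pr$rationale) |>
    distinct(.data$drug, .data$gene, .data$interaction, .data$tier,
             .data$source, .data$prioritized, .data$rationale) |>
    arrange(.data$drug, .data$gene, .data$source, .data$tier)
  gene_nodes <- matched |>
    distinct(.data$gene, .data$direction, .data$role, .data$meta_pathway_count) |>
    group_by(.data$gene, .data$direction, .data$role) |>
    summarise(meta_pathway_count = max(.data$meta_pathway_count), .groups = "drop") |>
    mutate(node = .data$gene, type = "gene",
           best_tier_civic = best_tier_for(.data$gene, edges, "civic"),
           best_tier_oncokb = best_tier_for(.data$gene, edges, "oncokb")) |>
    select("node", "type", "direction", "role", "meta_pathway_count",
           "best_tier_civic", "best_tier_oncokb")
  drug_nodes <- tibble(node = sort(unique(edges$drug)), type = "drug",
                       direction = NA_character_, role = NA_character_,
                       meta_pathway_count = NA_integer_) |>
    mutate(best_tier_civic = best_tier_for(.data$node, edges, "civic", by = "drug"),
           best_tier_oncokb = best_tier_for(.data$node, edges, "oncokb", by = "drug"))
  nodes <- bind_rows(drug_nodes, gene_nodes) |>
    mutate(meta_pathway_count = as.integer(.data$meta_pathway_count)) |>
    arrange(.data$type, .data$node)
  new_drug_target_network(nodes, edges)
}

best_tier_for <- function(ids, edges, src, by = "gene") {
  order_of <- if (src == "civic") CIVIC_TIERS else ONCOKB_TIERS
  vapply(ids, function(id) {
    tiers <- edges$tier[edges[[by]] == id & edges$source == src]
    if (length(tiers) == 0) return(NA_character_)
    order_of[min(match(tiers, order_of))]
  }, character(1), USE.NAMES = FALSE)
}

#' @exportS3Method generics::tidy
tidy.drug_target_network <- function(x, ...) x$edges

#' @exportS3Method generics::glance
glance.drug_target_network <- function(x, ...) {
  tibble(n_drugs = sum(x$nodes$type == "drug"),
         n_genes = sum(x$nodes$type == "gene"),
         n_edges = nrow(x$edges),
         n_prioritized = sum(x$edges$prioritized))
}

#' Per-gene druggability report
#'
#' One row per gene in the network: direction, pathway multiplicity, the
#' drugs and tiers attached to it, and how many of its relations are
#' prioritized.
#'
#' @param network A `drug_target_network`.
#' @return Tibble.
#' @export
druggability_report <- function(network) {
  genes <- network$nodes |> filter(.data$type == "gene")
  network$edges |>
    group_by(gene = .data$gene) |>
    summarise(
      drugs = paste(sort(unique(.data$drug)), collapse = ","),
      tiers = paste(sort(unique(paste0(.data$source, ":", .data$tier))),
                    collapse = ","),
      n_edges = dplyr::n(),
      n_prioritized = sum(.data$prioritized),
      .groups = "drop") |>
    left_join(genes |> select(gene = "node", "direction", "role",
                              "meta_pathway_count"),
              by = "gene") |>
    select("gene", "direction", "role", "meta_pathway_count", "drugs",
           "tiers", "n_edges", "n_prioritized") |>
    arrange(desc(.data$n_prioritized), .data$gene)
}
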