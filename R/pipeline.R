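# End-to-end orchestration: one config, deterministic stage seeding, stage
# outputs as plain-text tables, and a run manifest with checksums and the
# cohort funnel counts.

#' Pipeline configuration
#'
#' Either a `simulate` block (a [sim_config()]) or the full set of input
#' paths must be supplied. All of the screen's constants are configurable
#' here and default to the analysis profile of the motivating study:
#' selection cutoff R > 0.2 calibrated by 100,000 permutations, 100 resamples
#' of 50 controls against the below-median pool, q < 0.05 for pathway
#' significance, key-gene threshold R > 0.3, tier report at R > 0.5.
#'
#' @param simulate Optional [sim_config()]; when present, inputs are
#'   generated rather than read.
#' @param paths Named list of input paths (`expression`, `metadata`,
#'   `fusions`, `gmt`, `meta_map`, `census`, `civic`, `oncokb`); required
#'   when `simulate` is absent.
#' @param reference_gene Reference gene ID.
#' @param fusion_pair Length-2 character vector (5', 3' partner).
#' @param selection_cutoff,key_r_threshold,tier_cutoff,q_threshold Analysis
#'   cutoffs, each in `[0, 1]`.
#' @param n_resamples,control_size Resampling scheme of the screen.
#' @param n_permutations,calibration_mode Permutation calibration parameters.
#' @param transform Expression transform for the screen (`"none"` or
#'   `"log2p1"`).
#' @param seed Master seed; all stage seeds derive from it deterministically.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, paths = NULL,
                            reference_gene = "RSPO3",
                            fusion_pair = c("PTPRK", "RSPO3"),
                            selection_cutoff = 0.2, key_r_threshold = 0.3,
                            tier_cutoff = 0.5, q_threshold = 0.05,
                            n_resamples = 100L, control_size = 50L,
                            n_permutations = 100000L,
                            calibration_mode = c("full", "single"),
                            transform = c("none", "log2p1"),
                            seed = 1L) {
  calibration_mode <- match.arg(calibration_mode)
  transform <- match.arg(transform)
  required_paths <- c("expression", "metadata", "fusions", "gmt", "meta_map",
                      "census", "civic", "oncokb")
  if (is.null(simulate)) {
    if (is.null(paths)) stop_fs("either a simulate block or input paths are required")
    missing <- setdiff(required_paths, names(paths))
    if (length(missing) > 0) {
      stop_fs("configuration error: missing input path(s): %s",
              paste(missing, collapse = ", "))
    }
  } else if (!inherits(simulate, "sim_config")) {
    stop_fs("simulate block must be a sim_config")
  }
  for (ct in c("selection_cutoff", "key_r_threshold", "tier_cutoff", "q_threshold")) {
    check_prob(get(ct), ct)
  }
  structure(
    list(simulate = simulate, paths = paths, reference_gene = reference_gene,
         fusion_pair = fusion_pair, selection_cutoff = selection_cutoff,
         key_r_threshold = key_r_threshold, tier_cutoff = tier_cutoff,
         q_threshold = q_threshold,
         n_resamples = check_count(n_resamples, "n_resamples", 1L),
         control_size = check_count(control_size, "control_size", 1L),
         n_permutations = check_count(n_permutations, "n_permutations", 100L),
         calibration_mode = calibration_mode, transform = transform,
         seed = check_count(seed, "seed")),
    class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML schema mirrors the arguments of [pipeline_config()]; a
#' `simulate:` mapping is passed to [sim_config()], a `paths:` mapping lists
#' the input files.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) y$simulate <- do.call(sim_config, y$simulate)
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Executes cohort construction, the correlation screen, the permutation
#' calibration, the pathway enrichment with meta-pathway collapse and gene
#' annotation, and the drug-network stage, writing every stage output under
#' `outdir` together with a JSON run manifest (stage seeds, input checksums,
#' output checksums, and the cohort funnel counts). Two runs with the same
#' configuration produce byte-identical files.
#'
#' @param config A `pipeline_config`.
#' @param outdir Output directory (created if needed).
#' @param quiet Suppress stage progress messages.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, outdir, quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) stop_fs("config must be a pipeline_config")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  input_checksums <- list()

  if (!is.null(config$simulate)) {
    say("stage simulate: %d genes x %d samples", config$simulate$n_genes,
        config$simulate$n_tumor + config$simulate$n_normal + config$simulate$n_metastasis)
    cohort <- simulate_cohort(config$simulate)
    expr <- cohort$expression
    metadata <- cohort$metadata
    fusions <- cohort$fusion_calls
    kb_genes <- unique(c(config$reference_gene,
                         cohort$truth$gene_id[!is.na(cohort$truth$module)]))
    db <- simulate_pathway_db(genes = rownames(expr), planted = kb_genes,
                              seed = derive_seed(config$seed, "pathway_db"))
    kb <- simulate_drug_kb(kb_genes, seed = derive_seed(config$seed, "drug_kb"))
    pathways <- db$pathways; meta_map <- db$meta_map; census <- kb$census
    civic_path <- file.path(outdir, "civic_fixture.tsv")
    oncokb_path <- file.path(outdir, "oncokb_fixture.tsv")
    write_drug_kb(kb$civic, civic_path, "civic")
    write_drug_kb(kb$oncokb, oncokb_path, "oncokb")
    civic <- read_drug_kb(civic_path, "civic")
    oncokb <- read_drug_kb(oncokb_path, "oncokb")
    readr::write_tsv(cohort$truth, file.path(outdir, "truth.tsv"), na = "NA",
                     progress = FALSE)
  } else {
    say("stage load: reading inputs")
    p <- config$paths
    expr <- read_expression(p$expression)
    metadata <- read_metadata(p$metadata)
    fusions <- read_fusions(p$fusions)
    pathways <- read_gmt(p$gmt)
    meta_map <- read_meta_map(p$meta_map)
    census <- read_gene_list(p$census)
    civic <- read_drug_kb(p$civic, "civic")
    oncokb <- read_drug_kb(p$oncokb, "oncokb")
    input_checksums <- as.list(tools::md5sum(unlist(p)))
  }

  # cohort stage
  tumor_ids <- filter_tumor_samples(metadata)
  case_ids <- select_cases(fusions, expr, config$reference_gene, tumor_ids,
                           pair = config$fusion_pair)
  if (length(case_ids) < 2) stop_fs("cohort stage: fewer than 2 case samples")
  pool <- build_control_pool(expr, tumor_ids, case_ids, config$reference_gene)
  design <- draw_resamples(pool, case_ids, config$n_resamples,
                           config$control_size,
                           seed = derive_seed(config$seed, "resamples"))
  say("stage cohort: %d tumors, %d cases, pool %d", length(tumor_ids),
      length(case_ids), length(pool))
  write_cohort_design(design, file.path(outdir, "cohort_design.tsv"))
  clin <- clinical_comparison(metadata, case_ids, pool)
  readr::write_tsv(clin, file.path(outdir, "clinical_comparison.tsv"),
                   na = "NA", progress = FALSE)

  # screen stage
  screen <- run_screen(expr, design, config$reference_gene,
                       transform = config$transform,
                       cutoff = config$selection_cutoff)
  selected <- select_genes(screen, config$selection_cutoff)
  tier_genes <- select_genes(screen, config$tier_cutoff)
  say("stage screen: %d/%d genes selected at R > %.2f (%d at R > %.2f)",
      length(selected), nrow(screen), config$selection_cutoff,
      length(tier_genes), config$tier_cutoff)
  write_screen(screen, file.path(outdir, "screen.tsv"))
  if (length(selected) > 0) {
    zs <- zscore_matrix(expr, genes = head(selected, 500),
                        samples = c(design$case_ids, design$control_pool_ids))
    readr::write_tsv(tibble::as_tibble(zs, rownames = "gene_id"),
                     file.path(outdir, "zscore_selected.tsv"), progress = FALSE)
  }

  # calibration stage
  calib <- calibrate_cutoff(expr, design, config$reference_gene,
                            n_permutations = config$n_permutations,
                            mode = config$calibration_mode,
                            seed = derive_seed(config$seed, "calibration"),
                            transform = config$transform)
  say("stage calibrate: rate %.4f%% at cutoff %.2f (%s mode)",
      100 * calib$rate[match(config$selection_cutoff, calib$cutoff)],
      config$selection_cutoff, config$calibration_mode)
  write_calibration(calib, file.path(outdir, "calibration.tsv"))

  # enrichment stage
  universe <- annotated_universe(expr, pathways)
  query <- intersect(selected, universe)
  if (length(query) == 0) stop_fs("enrichment stage: no selected gene in the universe")
  ora <- ora_hypergeometric(query, pathways, universe)
  collapsed <- collapse_to_meta(ora, meta_map, pathways, query,
                                q_threshold = config$q_threshold)
  annotations <- annotate_genes(collapsed$component_genes, census, screen,
                                collapsed$meta_genes,
                                key_r_threshold = config$key_r_threshold)
  say("stage enrich: %d significant pathways, %d component genes, %d key genes",
      length(collapsed$significant), length(collapsed$component_genes),
      sum(annotations$key_gene))
  ora_out <- ora |> left_join(meta_map, by = "pathway_id") |>
    arrange(.data$q_value, .data$pathway_id)
  readr::write_tsv(ora_out, file.path(outdir, "enrichment.tsv"), na = "NA",
                   progress = FALSE)
  readr::write_tsv(collapsed$meta_genes, file.path(outdir, "meta_pathway_genes.tsv"),
                   progress = FALSE)
  readr::write_tsv(annotations, file.path(outdir, "gene_annotations.tsv"),
                   na = "NA", progress = FALSE)
  write_gene_directions(annotations, file.path(outdir, "gene_directions.tsv"))

  # drug-network stage
  matches <- match_actionable(annotations, civic, oncokb)
  network <- build_network(matches$matched)
  say("stage drugs: %d matched genes, %d edges (%d prioritized)",
      dplyr::n_distinct(matches$matched$gene), nrow(network$edges),
      sum(network$edges$prioritized))
  write_network(network, file.path(outdir, "drug_network"))
  readr::write_tsv(druggability_report(network),
                   file.path(outdir, "druggability_report.tsv"),
                   na = "NA", progress = FALSE)
  readr::write_lines(matches$unmatched, file.path(outdir, "undruggable_genes.txt"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("fusionscreen")),
    seed = config$seed,
    stage_seeds = list(resamples = derive_seed(config$seed, "resamples"),
                       calibration = derive_seed(config$seed, "calibration"),
                       pathway_db = derive_seed(config$seed, "pathway_db"),
                       drug_kb = derive_seed(config$seed, "drug_kb")),
    parameters = config[c("reference_gene", "fusion_pair", "selection_cutoff",
                          "key_r_threshold", "tier_cutoff", "q_threshold",
                          "n_resamples", "control_size", "n_permutations",
                          "calibration_mode", "transform")],
    input_checksums = input_checksums,
    funnel = list(
      n_samples = nrow(metadata),
      n_tumor = length(tumor_ids),
      n_cases = length(case_ids),
      n_noncase_tumor = length(tumor_ids) - length(case_ids),
      pool_size = length(pool),
      n_genes = nrow(expr),
      n_selected = length(selected),
      n_tier = length(tier_genes),
      n_pathways_significant = length(collapsed$significant),
      n_component_genes = length(collapsed$component_genes),
      n_cancer_genes = sum(annotations$is_cancer_gene),
      n_key_genes = sum(annotations$key_gene),
      n_druggable_genes = dplyr::n_distinct(matches$matched$gene),
      n_edges = nrow(network$edges),
      n_prioritized_edges = sum(network$edges$prioritized)),
    outputs = NULL)
  out_files <- sort(setdiff(list.files(outdir, full.names = TRUE),
                            file.path(outdir, "manifest.json")))
  manifest$outputs <- as.list(tools::md5sum(out_files))
  names(manifest$outputs) <- basename(out_files)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(design = design, screen = screen, calibration = calib,
                 enrichment = ora, collapsed = collapsed,
                 annotations = annotations, network = network,
                 clinical = clin, manifest = manifest))
}
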