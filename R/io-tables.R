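# Readers/writers for the tabular dialects around the pipeline: clinical
# metadata, fusion calls, GMT gene sets, meta-pathway maps, cancer-gene
# lists, and the CIViC/OncoKB drug-evidence dialects. All schemas are frozen
# minimal versions of the upstream downloads (whose live schemas drift).

SAMPLE_TYPES <- c("tumor", "normal", "metastasis")
SEX_LEVELS <- c("male", "female")
VITAL_LEVELS <- c("alive", "dead")
STAGE_LEVELS <- c("I", "II", "III", "IV")
MSI_LEVELS <- c("MSI-high", "MSI-low", "MSS")
HISTOLOGY_LEVELS <- c("adenocarcinoma", "mucinous adenocarcinoma")
ROLE_LEVELS <- c("oncogene", "tumor_suppressor", "both", "unknown")
INTERACTION_LEVELS <- c("inhibits", "activates", "other")
CIVIC_TIERS <- c("A", "B", "C", "D", "E")
ONCOKB_TIERS <- c("1", "2", "3", "4")

read_tsv_strict <- function(path, required) {
  if (!file.exists(path)) stop_fs("file not found: %s", path)
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       na = c("", "NA"), progress = FALSE)
  missing <- setdiff(required, colnames(x))
  if (length(missing) > 0) {
    stop_fs("%s: missing mandatory column(s): %s", path, paste(missing, collapse = ", "))
  }
  x
}

check_vocab <- function(x, levels, field, path) {
  bad <- setdiff(unique(x[!is.na(x)]), levels)
  if (length(bad) > 0) {
    stop_fs("%s: invalid %s value(s): %s (allowed: %s)", path, field,
            paste(bad, collapse = ", "), paste(levels, collapse = ", "))
  }
  x
}

#' Read a clinical sample metadata table
#'
#' Mandatory columns `sample_id` and `sample_type` (tumor/normal/metastasis);
#' optional clinical covariates (`age`, `sex`, `vital_status`, `stage`,
#' `msi_status`, `histology`) and logical mutation flags (`mut_*` columns).
#' Empty strings and `"NA"` are both read as missing. Categorical fields are
#' validated against their controlled vocabularies.
#'
#' @param path TSV path.
#' @return Tibble, one row per sample.
#' @export
read_metadata <- function(path) {
  x <- read_tsv_strict(path, c("sample_id", "sample_type"))
  if (anyDuplicated(x$sample_id)) {
    stop_fs("%s: duplicate sample_id: %s", path,
            paste(unique(x$sample_id[duplicated(x$sample_id)]), collapse = ", "))
  }
  check_vocab(x$sample_type, SAMPLE_TYPES, "sample_type", path)
  vocabs <- list(sex = SEX_LEVELS, vital_status = VITAL_LEVELS,
                 stage = STAGE_LEVELS, msi_status = MSI_LEVELS,
                 histology = HISTOLOGY_LEVELS)
  for (f in names(vocabs)) {
    if (f %in% colnames(x)) check_vocab(x[[f]], vocabs[[f]], f, path)
  }
  if ("age" %in% colnames(x)) x$age <- as.numeric(x$age)
  for (f in grep("^mut_", colnames(x), value = TRUE)) {
    x[[f]] <- as.logical(x[[f]])
  }
  x
}

#' @rdname read_metadata
#' @param metadata Tibble as returned by [read_metadata()] or the simulator.
#' @export
write_metadata <- function(metadata, path) {
  readr::write_tsv(metadata, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read/write a fusion call table
#'
#' Minimal dialect: columns `sample_id`, `gene_5prime`, `gene_3prime`, one
#' row per called fusion. Duplicate (sample, pair) rows are rejected.
#'
#' @param path TSV path.
#' @return Tibble of fusion calls.
#' @export
read_fusions <- function(path) {
  x <- read_tsv_strict(path, c("sample_id", "gene_5prime", "gene_3prime"))
  if (anyDuplicated(x[, c("sample_id", "gene_5prime", "gene_3prime")])) {
    stop_fs("%s: duplicate (sample, fusion pair) rows", path)
  }
  x
}

#' @rdname read_fusions
#' @param fusions Tibble of fusion calls.
#' @export
write_fusions <- function(fusions, path) {
  readr::write_tsv(fusions, path, progress = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one pathway per line, tab-separated
#' `name <TAB> description <TAB> gene1 <TAB> gene2 ...`. Empty gene sets and
#' duplicate pathway names are rejected.
#'
#' @param path GMT path.
#' @return Tibble with `pathway_id`, `source` (the description field) and a
#'   `genes` list-column.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_fs("file not found: %s", path)
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop_fs("empty GMT file: %s", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad) > 0) {
    stop_fs("%s: line %d has no genes (GMT needs name, description, >=1 gene)",
            path, bad[1])
  }
  ids <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(ids)) {
    stop_fs("%s: duplicate pathway id: %s", path,
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  tibble(pathway_id = ids,
         source = vapply(parts, `[[`, character(1), 2),
         genes = lapply(parts, function(p) unique(p[-(1:2)])))
}

#' @rdname read_gmt
#' @param db Pathway tibble (`pathway_id`, `source`, `genes` list-column).
#' @export
write_gmt <- function(db, path) {
  lines <- vapply(seq_len(nrow(db)), function(i) {
    paste(c(db$pathway_id[i], db$source[i], db$genes[[i]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read/write a meta-pathway map
#'
#' Two-column TSV `meta`, `pathway_id` assigning source pathways to named
#' meta-pathway groups.
#'
#' @param path TSV path.
#' @return Tibble with columns `meta` and `pathway_id`.
#' @export
read_meta_map <- function(path) {
  x <- read_tsv_strict(path, c("meta", "pathway_id"))
  if (anyDuplicated(x$pathway_id)) {
    stop_fs("%s: pathway mapped to more than one meta-pathway", path)
  }
  x
}

#' @rdname read_meta_map
#' @param map Meta-map tibble.
#' @export
write_meta_map <- function(map, path) {
  readr::write_tsv(map[, c("meta", "pathway_id")], path, progress = FALSE)
  invisible(path)
}

#' Read/write a cancer-gene list
#'
#' Census-style table: columns `gene` and `role`
#' (oncogene / tumor_suppressor / both / unknown); genes must be unique.
#'
#' @param path TSV path.
#' @return Tibble with `gene`, `role`.
#' @export
read_gene_list <- function(path) {
  x <- read_tsv_strict(path, c("gene", "role"))
  if (anyDuplicated(x$gene)) {
    stop_fs("%s: duplicate gene: %s", path,
            paste(unique(x$gene[duplicated(x$gene)]), collapse = ", "))
  }
  x$role[is.na(x$role)] <- "unknown"
  check_vocab(x$role, ROLE_LEVELS, "role", path)
  x[, c("gene", "role")]
}

#' @rdname read_gene_list
#' @param genes Tibble with `gene` and `role`.
#' @export
write_gene_list <- function(genes, path) {
  readr::write_tsv(genes[, c("gene", "role")], path, progress = FALSE)
  invisible(path)
}

#' Read a drug-evidence knowledgebase table
#'
#' Frozen minimal dialects of the CIViC "Clinical Evidence Summaries" and
#' OncoKB "Actionable Variants" downloads. Both are TSVs with columns
#' `gene`, `drugs`, `interaction`, a tier column (`evidence_level`, A-E, for
#' `dialect = "civic"`; `level`, 1-4, for `dialect = "oncokb"`), `gene_role`
#' and `disease`. Multi-drug cells are split on `","` into one evidence row
#' per drug. Tiers and interactions outside the controlled sets are rejected.
#'
#' @param path TSV path.
#' @param dialect `"civic"` or `"oncokb"`.
#' @return Tibble of evidence rows: `gene`, `drug`, `interaction`, `tier`,
#'   `gene_role`, `disease`, `source`.
#' @export
read_drug_kb <- function(path, dialect = c("civic", "oncokb")) {
  dialect <- match.arg(dialect)
  tier_col <- if (dialect == "civic") "evidence_level" else "level"
  tiers <- if (dialect == "civic") CIVIC_TIERS else ONCOKB_TIERS
  x <- read_tsv_strict(path, c("gene", "drugs", "interaction", tier_col))
  if (any(is.na(x$gene) | !nzchar(x$gene))) stop_fs("%s: empty gene field", path)
  check_vocab(x$interaction, INTERACTION_LEVELS, "interaction", path)
  check_vocab(x[[tier_col]], tiers, tier_col, path)
  if (!"gene_role" %in% colnames(x)) x$gene_role <- "unknown"
  x$gene_role[is.na(x$gene_role)] <- "unknown"
  check_vocab(x$gene_role, ROLE_LEVELS, "gene_role", path)
  if (!"disease" %in% colnames(x)) x$disease <- NA_character_
  out <- tibble(gene = x$gene, drugs = x$drugs, interaction = x$interaction,
                tier = x[[tier_col]], gene_role = x$gene_role,
                disease = x$disease) |>
    mutate(drug = strsplit(.data$drugs, ",", fixed = TRUE)) |>
    tidyr::unnest("drug") |>
    mutate(drug = stringr::str_trim(.data$drug), source = dialect) |>
    select("gene", "drug", "interaction", "tier", "gene_role", "disease", "source")
  if (any(!nzchar(out$drug))) stop_fs("%s: empty drug name after splitting", path)
  out
}

#' @rdname read_drug_kb
#' @param kb Wide evidence tibble (`gene`, `drugs`, `interaction`,
#'   `evidence_tier`, `gene_role`, `disease`), e.g. from [simulate_drug_kb()].
#' @export
write_drug_kb <- function(kb, path, dialect = c("civic", "oncokb")) {
  dialect <- match.arg(dialect)
  tier_col <- if (dialect == "civic") "evidence_level" else "level"
  out <- kb[, c("gene", "drugs", "interaction", "evidence_tier", "gene_role", "disease")]
  colnames(out)[colnames(out) == "evidence_tier"] <- tier_col
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
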