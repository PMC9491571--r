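# Cohort construction: tumor filtering, fusion-positive case selection with
# an expression elevation cross-check, the low-expression control pool, the
# resampled control sets, and the Table-1-style clinical comparison.

#' Keep only primary tumor samples
#'
#' @param metadata Sample metadata tibble with `sample_id` and `sample_type`.
#' @return Character vector of tumor sample IDs, in input order.
#' @export
filter_tumor_samples <- function(metadata) {
  if (!all(c("sample_id", "sample_type") %in% colnames(metadata))) {
    stop_fs("metadata needs sample_id and sample_type columns")
  }
  metadata$sample_id[metadata$sample_type %in% "tumor"]
}

#' Select fusion-positive case samples
#'
#' Cases are tumor samples carrying the named fusion pair whose
#' reference-gene expression also passes the elevation cross-check
#' (default: strictly above the median reference-gene expression across all
#' tumor samples). An empty result (no calls for the pair, or none elevated)
#' warns rather than errors.
#'
#' @param fusions Fusion call tibble (`sample_id`, `gene_5prime`, `gene_3prime`).
#' @param expr Expression matrix (genes x samples).
#' @param reference_gene Reference gene ID (must be present in `expr`).
#' @param tumor_ids Tumor sample IDs defining the cohort (and the median).
#' @param pair Length-2 character vector: 5' and 3' fusion partner.
#' @param elevation_rule `"above_median"` (default) or `"none"`.
#' @return Character vector of case sample IDs (order of `tumor_ids`).
#' @export
select_cases <- function(fusions, expr, reference_gene, tumor_ids,
                         pair = c("PTPRK", "RSPO3"),
                         elevation_rule = c("above_median", "none")) {
  elevation_rule <- match.arg(elevation_rule)
  if (!reference_gene %in% rownames(expr)) {
    stop_fs("reference gene %s absent from expression matrix", reference_gene)
  }
  if (!all(tumor_ids %in% colnames(expr))) {
    stop_fs("tumor_ids not all present in expression matrix")
  }
  hit <- fusions$sample_id[fusions$gene_5prime == pair[1] &
                             fusions$gene_3prime == pair[2]]
  cases <- intersect(tumor_ids, hit)
  if (length(cases) == 0) {
    warn(sprintf("no fusion calls for pair %s-%s among tumor samples",
                 pair[1], pair[2]))
    return(character(0))
  }
  if (elevation_rule == "above_median") {
    ref <- expr[reference_gene, tumor_ids]
    cases <- cases[expr[reference_gene, cases] > median(ref)]
    if (length(cases) == 0) {
      warn("all fusion-positive samples failed the elevation cross-check")
    }
  }
  tumor_ids[tumor_ids %in% cases]
}

#' Build the low-expression control pool
#'
#' Among the non-case tumor samples, returns those whose reference-gene
#' expression is strictly below the median reference-gene expression over
#' that same non-case set (even counts: median is the mean of the two
#' central order statistics). With distinct values over an even count this
#' is exactly half the non-case samples.
#'
#' @inheritParams select_cases
#' @param case_ids Case sample IDs (subset of `tumor_ids`).
#' @return Character vector of control-pool sample IDs.
#' @export
build_control_pool <- function(expr, tumor_ids, case_ids, reference_gene) {
  if (!all(case_ids %in% tumor_ids)) stop_fs("case_ids must be a subset of tumor_ids")
  noncase <- setdiff(tumor_ids, case_ids)
  if (length(noncase) < 2) stop_fs("fewer than 2 non-case tumor samples")
  ref <- expr[reference_gene, noncase]
  pool <- noncase[ref < median(ref)]
  if (length(pool) == 0) {
    stop_fs("empty control pool: reference-gene values are tied at the median")
  }
  pool
}

#' Draw resampled control sets
#'
#' Draws `n_resamples` control sets of `control_size` samples each,
#' uniformly without replacement from the control pool, independently across
#' resamples. Together with the case IDs this defines the sampling scheme of
#' the correlation screen.
#'
#' @param pool Control-pool sample IDs.
#' @param case_ids Fusion-positive case sample IDs (disjoint from `pool`,
#'   at least 2).
#' @param n_resamples Number of resampled control sets (default 100).
#' @param control_size Samples per control set (default 50).
#' @param seed Integer seed; draws are reproducible.
#' @return A `cohort_design` object.
#' @export
draw_resamples <- function(pool, case_ids, n_resamples = 100L,
                           control_size = 50L, seed = 1L) {
  n_resamples <- check_count(n_resamples, "n_resamples", min = 1L)
  control_size <- check_count(control_size, "control_size", min = 1L)
  if (length(case_ids) < 2) stop_fs("need at least 2 case samples")
  if (length(intersect(pool, case_ids)) > 0) {
    stop_fs("control pool and cases must be disjoint")
  }
  if (length(pool) < control_size) {
    stop_fs("control pool (%d) smaller than control_size (%d)",
            length(pool), control_size)
  }
  sets <- with_seed(seed, {
    lapply(seq_len(n_resamples), function(i) sample(pool, control_size))
  })
  structure(list(case_ids = case_ids, control_pool_ids = pool,
                 n_resamples = n_resamples, control_size = control_size,
                 seed = check_count(seed, "seed"), resample_sets = sets),
            class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat("<cohort_design> ", length(x$case_ids), " cases; pool of ",
      length(x$control_pool_ids), "; ", x$n_resamples, " resamples of ",
      x$control_size, " controls (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cohort_design <- function(x, ...) {
  tibble(resample = rep(seq_len(x$n_resamples), each = x$control_size),
         sample_id = unlist(x$resample_sets))
}

#' @exportS3Method generics::glance
glance.cohort_design <- function(x, ...) {
  tibble(n_cases = length(x$case_ids), pool_size = length(x$control_pool_ids),
         n_resamples = x$n_resamples, control_size = x$control_size,
         seed = x$seed)
}

#' Write a cohort design as TSV (one row per resample)
#'
#' @param design A `cohort_design`.
#' @param path Output path.
#' @export
write_cohort_design <- function(design, path) {
  out <- tibble(
    resample = seq_len(design$n_resamples),
    control_ids = vapply(design$resample_sets, paste, character(1), collapse = ","))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Clinical comparison between cases and controls
#'
#' Table-1-style comparison: categorical covariates by two-sided Fisher exact
#' test (2 x k), continuous covariates (age) by Wilcoxon rank-sum. Missing
#' values are dropped per variable; the per-variable group denominators are
#' reported, so the denominators can differ across variables.
#'
#' @param metadata Sample metadata tibble.
#' @param case_ids,control_ids Sample IDs of the two groups.
#' @param variables Covariates to compare; defaults to the clinical covariates
#'   and mutation flags present in `metadata`.
#' @return Tibble: variable, test, per-group non-missing counts, group
#'   summaries, p-value.
#' @export
clinical_comparison <- function(metadata, case_ids, control_ids,
                                variables = NULL) {
  if (length(case_ids) == 0 || length(control_ids) == 0) {
    stop_fs("both groups must be non-empty")
  }
  if (is.null(variables)) {
    variables <- intersect(
      c("age", "sex", "vital_status", "stage", "msi_status", "histology",
        grep("^mut_", colnames(metadata), value = TRUE)),
      colnames(metadata))
  }
  absent <- setdiff(variables, colnames(metadata))
  if (length(absent) > 0) {
    stop_fs("variable(s) absent from metadata: %s", paste(absent, collapse = ", "))
  }
  md <- metadata[match(c(case_ids, control_ids), metadata$sample_id), ]
  grp <- rep(c("fusion", "control"), c(length(case_ids), length(control_ids)))
  purrr::map_dfr(variables, function(v) {
    x <- md[[v]]
    keep <- !is.na(x)
    xv <- x[keep]; gv <- grp[keep]
    n_f <- sum(gv == "fusion"); n_c <- sum(gv == "control")
    if (is.numeric(xv)) {
      p <- if (n_f > 0 && n_c > 0) {
        suppressWarnings(wilcox.test(xv[gv == "fusion"], xv[gv == "control"])$p.value)
      } else NA_real_
      tibble(variable = v, test = "wilcoxon", n_fusion = n_f, n_control = n_c,
             fusion_summary = summarise_num(xv[gv == "fusion"]),
             control_summary = summarise_num(xv[gv == "control"]),
             p_value = p)
    } else {
      xv <- as.character(xv)
      tab <- table(factor(gv, c("fusion", "control")), xv)
      p <- if (n_f > 0 && n_c > 0 && ncol(tab) >= 2) {
        fisher.test(tab, workspace = 2e7)$p.value
      } else NA_real_
      tibble(variable = v, test = "fisher", n_fusion = n_f, n_control = n_c,
             fusion_summary = summarise_cat(xv[gv == "fusion"]),
             control_summary = summarise_cat(xv[gv == "control"]),
             p_value = p)
    }
  })
}

summarise_num <- function(x) {
  if (length(x) == 0) return(NA_character_)
  sprintf("%s~%s", format(min(x)), format(max(x)))
}

summarise_cat <- function(x) {
  if (length(x) == 0) return(NA_character_)
  tab <- table(x)
  paste(sprintf("%s:%d/%d", names(tab), as.integer(tab), length(x)), collapse = "; ")
}
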