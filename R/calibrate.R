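# Permutation calibration of the selection cutoff: estimate the fraction of
# null genes (randomly reordered expression values) whose selection statistic
# exceeds each candidate cutoff.

#' Permutation calibration of the correlation cutoff
#'
#' Each permutation picks a random gene and randomly reorders its expression
#' values across the cohort samples (cases plus control pool), then computes
#' a null selection statistic:
#' \describe{
#'   \item{`mode = "single"`}{one absolute Pearson R against the reference
#'     gene on one assembled case + control set (the literal single-test
#'     null; the set is drawn at random among the design's resample sets);}
#'   \item{`mode = "full"`}{the complete screen statistic — the median
#'     absolute Pearson R across all of the design's resampled control sets
#'     (the default, mirroring the selection procedure exactly).}
#' }
#' The curve reports, per cutoff, the fraction of null statistics strictly
#' exceeding it. The two modes answer different questions and can differ
#' substantially: the median over resamples concentrates, so the full-mode
#' exceedance at any positive cutoff is at most the single-mode one up to
#' Monte-Carlo noise.
#'
#' @inheritParams run_screen
#' @param n_permutations Number of permutation tests (>= 100; default 100,000).
#' @param cutoffs Cutoff grid in `[0, 1]`.
#' @param mode `"full"` or `"single"`.
#' @param seed Integer seed for gene draws and reorderings.
#' @param keep_stats If `TRUE`, the per-permutation null statistics (and, in
#'   single mode, the signed null correlations) are attached as attributes
#'   `"stats"` / `"null_r"` for diagnostics.
#' @return A `calibration_curve` tibble: `cutoff`, `rate`, `n_permutations`,
#'   `mode`, `seed`; rates are non-increasing in the cutoff.
#' @export
calibrate_cutoff <- function(expr, design, reference_gene,
                             n_permutations = 100000L,
                             cutoffs = c(0.05, 0.1, 0.15, 0.2, 0.25, 0.3, 0.4, 0.5),
                             mode = c("full", "single"), seed = 1L,
                             transform = c("none", "log2p1"),
                             batch_size = 512L, keep_stats = FALSE) {
  mode <- match.arg(mode)
  transform <- match.arg(transform)
  assert_expression_matrix(expr)
  n_permutations <- check_count(n_permutations, "n_permutations", min = 100L)
  if (any(cutoffs < 0 | cutoffs > 1)) stop_fs("cutoffs must lie in [0, 1]")
  if (!reference_gene %in% rownames(expr)) {
    stop_fs("reference gene %s absent from expression matrix", reference_gene)
  }
  x <- apply_transform(expr, transform)
  universe <- c(design$case_ids, design$control_pool_ids)
  uni_idx <- match(universe, colnames(x))
  if (anyNA(uni_idx)) stop_fs("design sample(s) absent from expression matrix")
  # resample-set columns re-expressed as positions within the permutation
  # universe
  idx_global <- resample_index_matrix(design, colnames(x))
  idx <- matrix(match(idx_global, uni_idx), nrow(idx_global), ncol(idx_global))
  if (anyNA(idx)) stop_fs("resample sets must be drawn from cases + control pool")
  ref <- x[reference_gene, uni_idx]
  gene_pool <- setdiff(seq_len(nrow(x)), match(reference_gene, rownames(x)))
  s_len <- length(uni_idx)
  n_sets <- nrow(idx)

  stats <- numeric(n_permutations)
  null_r <- if (mode == "single") numeric(n_permutations) else NULL
  with_seed(seed, {
    for (start in seq(1L, n_permutations, by = batch_size)) {
      rows <- start:min(start + batch_size - 1L, n_permutations)
      b <- length(rows)
      g <- sample(gene_pool, b, replace = TRUE)
      vals <- x[g, uni_idx, drop = FALSE]
      ord <- vapply(seq_len(b), function(i) sample.int(s_len), integer(s_len))
      perm <- matrix(vals[(t(ord) - 1L) * b + seq_len(b)], b, s_len)
      if (mode == "full") {
        r <- screen_cor_matrix(perm, ref, idx)
        stats[rows] <- apply(abs(r), 1, median)
      } else {
        set_of <- sample.int(n_sets, b, replace = TRUE)
        for (s in unique(set_of)) {
          in_s <- which(set_of == s)
          r <- screen_cor_matrix(perm[in_s, , drop = FALSE], ref,
                                 idx[s, , drop = FALSE])
          null_r[rows[in_s]] <- r[, 1]
        }
        stats[rows] <- abs(null_r[rows])
      }
    }
  })
  out <- tibble(cutoff = sort(cutoffs), n_permutations = n_permutations,
                mode = mode, seed = check_count(seed, "seed")) |>
    mutate(rate = vapply(.data$cutoff, function(ct) mean(stats > ct), numeric(1))) |>
    select("cutoff", "rate", "n_permutations", "mode", "seed")
  if (keep_stats) {
    attr(out, "stats") <- stats
    attr(out, "null_r") <- null_r
  }
  class(out) <- c("calibration_curve", class(out))
  out
}

#' @exportS3Method generics::glance
glance.calibration_curve <- function(x, ...) {
  tibble(n_permutations = x$n_permutations[1], mode = x$mode[1],
         seed = x$seed[1], n_cutoffs = nrow(x),
         rate_at_0.2 = x$rate[match(0.2, x$cutoff)])
}

#' Write a calibration curve as TSV
#'
#' @param curve A `calibration_curve`.
#' @param path Output path.
#' @export
write_calibration <- function(curve, path) {
  readr::write_tsv(curve[, c("cutoff", "rate", "n_permutations", "mode", "seed")],
                   path, progress = FALSE)
  invisible(path)
}
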