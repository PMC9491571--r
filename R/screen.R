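# The resampled reference-gene correlation screen: per-gene Pearson R with
# the reference gene over cases + resampled controls, summarized by the
# median absolute R across resamples and thresholded at a calibrated cutoff.

#' Pearson correlation with a degenerate-variance placeholder
#'
#' Plain sample Pearson correlation of two equal-length vectors (length >= 3).
#' If either vector has zero variance the correlation is undefined; this
#' returns 0 carrying attribute `degenerate = TRUE` instead of `NA`, so
#' downstream medians over fixed-length resample vectors stay well defined.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Numeric scalar in `[-1, 1]` with attribute `degenerate`.
#' @export
#' @examples
#' pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.8
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop_fs("x and y must have equal length")
  if (length(x) < 3) stop_fs("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop_fs("missing values not allowed")
  if (sd(x) == 0 || sd(y) == 0) {
    return(structure(0, degenerate = TRUE))
  }
  structure(unname(cor(x, y)), degenerate = FALSE)
}

# Integer index matrix (n_sets x (n_cases + control_size)) of expr columns,
# cases first, one row per resample set.
resample_index_matrix <- function(design, sample_ids) {
  all_ids <- c(design$case_ids, unlist(design$resample_sets))
  missing <- setdiff(unique(all_ids), sample_ids)
  if (length(missing) > 0) {
    stop_fs("design sample(s) absent from expression matrix: %s",
            paste(head(missing, 5), collapse = ", "))
  }
  case_idx <- match(design$case_ids, sample_ids)
  t(vapply(design$resample_sets,
           function(s) c(case_idx, match(s, sample_ids)),
           integer(length(design$case_ids) + design$control_size)))
}

# Correlations of many value rows against a reference vector over many
# resample sets at once. values: B x S matrix; ref: length S; idx: n_sets x k
# column-index matrix. Returns B x n_sets matrix of Pearson R (0 where the
# row or the reference is constant within a set). Vectorized with one sparse
# block-aggregation matrix per call; the hot path of both the screen and the
# permutation calibration.
screen_cor_matrix <- function(values, ref, idx) {
  n_sets <- nrow(idx); k <- ncol(idx)
  idx_flat <- as.vector(t(idx))
  yc_list <- lapply(seq_len(n_sets), function(s) {
    y <- ref[idx[s, ]]
    yc <- y - mean(y)
    ny <- sqrt(sum(yc^2))
    if (ny == 0) rep(0, k) else yc / ny
  })
  w_flat <- unlist(yc_list)
  blocks <- rep(seq_len(n_sets), each = k)
  W <- Matrix::sparseMatrix(i = seq_along(idx_flat), j = blocks, x = w_flat,
                            dims = c(length(idx_flat), n_sets))
  P <- Matrix::sparseMatrix(i = seq_along(idx_flat), j = blocks, x = 1,
                            dims = c(length(idx_flat), n_sets))
  A <- values[, idx_flat, drop = FALSE]
  s1 <- as.matrix(A %*% W)
  sx <- as.matrix(A %*% P)
  sxx <- as.matrix((A * A) %*% P)
  denom2 <- sxx - sx^2 / k
  # guard: zero-variance rows within a set, and sets with constant reference
  tol <- pmax(sxx, 1) * 1e-12
  ok <- denom2 > tol
  ref_ok <- vapply(yc_list, function(w) any(w != 0), logical(1))
  r <- matrix(0, nrow(values), n_sets)
  denom <- sqrt(pmax(denom2, 0))
  r[ok] <- s1[ok] / denom[ok]
  r[, !ref_ok] <- 0
  pmin(pmax(r, -1), 1)
}

apply_transform <- function(x, transform) {
  switch(transform, none = x, log2p1 = log2(x + 1),
         stop_fs("unknown transform: %s", transform))
}

#' Run the resampled correlation screen
#'
#' For every gene and every resampled control set, computes the Pearson
#' correlation between that gene and the reference gene over the pooled
#' cases + controls, then summarizes each gene by the median absolute R and
#' the median signed R across resamples. Genes are ranked by decreasing
#' median |R| with lexicographic gene-ID tie-break; the reference gene
#' itself is included (median |R| = 1, rank 1). Zero-variance resamples
#' contribute R = 0 rather than being dropped, keeping the per-gene R vector
#' at a fixed length; a gene degenerate in every resample (e.g. all-zero
#' expression) gets median |R| = 0 and direction `"flat"`.
#'
#' @param expr Expression matrix (genes x samples).
#' @param design A [draw_resamples()] cohort design.
#' @param reference_gene Reference gene ID.
#' @param transform `"none"` (correlate raw normalized values, the default)
#'   or `"log2p1"` (correlate `log2(x + 1)`).
#' @param cutoff Selection cutoff on median |R| (strict `>`; default 0.2).
#' @param batch_size Genes per vectorized batch.
#' @return A `screen_result` tibble: `gene_id`, `median_abs_r`,
#'   `median_signed_r`, `direction` (up/down/flat), `n_degenerate`,
#'   `degenerate`, `selected`, `rank`; ordered by rank.
#' @export
run_screen <- function(expr, design, reference_gene,
                       transform = c("none", "log2p1"), cutoff = 0.2,
                       batch_size = 512L) {
  transform <- match.arg(transform)
  assert_expression_matrix(expr)
  if (!inherits(design, "cohort_design")) stop_fs("design must be a cohort_design")
  if (!reference_gene %in% rownames(expr)) {
    stop_fs("reference gene %s absent from expression matrix", reference_gene)
  }
  check_prob(cutoff, "cutoff")
  x <- apply_transform(expr, transform)
  idx <- resample_index_matrix(design, colnames(x))
  ref <- x[reference_gene, ]
  n_genes <- nrow(x)
  med_abs <- med_signed <- numeric(n_genes)
  n_deg <- integer(n_genes)
  for (start in seq(1L, n_genes, by = batch_size)) {
    rows <- start:min(start + batch_size - 1L, n_genes)
    r <- screen_cor_matrix(x[rows, , drop = FALSE], ref, idx)
    med_abs[rows] <- apply(abs(r), 1, median)
    med_signed[rows] <- apply(r, 1, median)
    n_deg[rows] <- rowSums(r == 0)
  }
  out <- tibble(
    gene_id = rownames(x),
    median_abs_r = med_abs,
    median_signed_r = med_signed,
    direction = direction_of(med_signed),
    n_degenerate = n_deg,
    degenerate = n_deg == nrow(idx)
  ) |>
    arrange(desc(.data$median_abs_r), .data$gene_id) |>
    mutate(rank = row_number(), selected = .data$median_abs_r > cutoff)
  attr(out, "cutoff") <- cutoff
  attr(out, "transform") <- transform
  attr(out, "reference_gene") <- reference_gene
  class(out) <- c("screen_result", class(out))
  out
}

#' @exportS3Method generics::glance
glance.screen_result <- function(x, ...) {
  tibble(n_genes = nrow(x), n_selected = sum(x$selected),
         n_degenerate = sum(x$degenerate),
         cutoff = attr(x, "cutoff"), transform = attr(x, "transform"),
         reference_gene = attr(x, "reference_gene"))
}

#' Select genes above a median-|R| cutoff
#'
#' Strict inequality (`median |R| > cutoff`), returned in rank order.
#'
#' @param records A `screen_result` tibble.
#' @param cutoff Cutoff in `[0, 1]` (default 0.2).
#' @return Character vector of selected gene IDs.
#' @export
select_genes <- function(records, cutoff = 0.2) {
  check_prob(cutoff, "cutoff")
  records <- dplyr::arrange(records, .data$rank)
  records$gene_id[records$median_abs_r > cutoff]
}

#' Row-wise z-score matrix
#'
#' Per-gene z-scores over the requested samples (heatmap substrate), using
#' the sample (n - 1) standard deviation; constant rows map to all zeros.
#'
#' @param expr Expression matrix.
#' @param genes,samples Identifiers to include (defaults: all).
#' @return Numeric matrix of z-scores, genes x samples.
#' @export
zscore_matrix <- function(expr, genes = rownames(expr), samples = colnames(expr)) {
  if (length(genes) == 0 || length(samples) == 0) stop_fs("empty gene/sample selection")
  missing <- setdiff(genes, rownames(expr))
  if (length(missing) > 0) stop_fs("gene(s) absent: %s", paste(head(missing, 5), collapse = ", "))
  missing <- setdiff(samples, colnames(expr))
  if (length(missing) > 0) stop_fs("sample(s) absent: %s", paste(head(missing, 5), collapse = ", "))
  m <- expr[genes, samples, drop = FALSE]
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  z <- (m - mu) / ifelse(s == 0, 1, s)
  z[s == 0, ] <- 0
  z
}

#' Write screen results as TSV
#'
#' @param records A `screen_result`.
#' @param path Output path.
#' @export
write_screen <- function(records, path) {
  readr::write_tsv(
    records[, c("gene_id", "median_abs_r", "median_signed_r", "direction",
                "selected", "rank")],
    path, progress = FALSE)
  invisible(path)
}
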