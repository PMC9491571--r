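# Expression matrix IO: genes-in-rows TSV, GDAC-style.

#' Read a gene x sample expression matrix from TSV
#'
#' Expects a tab-separated file with gene identifiers in the first column and
#' a header row of sample identifiers (the GDAC genes-in-rows convention);
#' `transpose = TRUE` accepts samples-in-rows input. TCGA-style composite
#' identifiers `"SYMBOL|EntrezID"` are split on the first `|` and the symbol
#' kept as the primary key. All values must be finite, numeric and
#' non-negative; violations are reported with their row and column location.
#'
#' @param path Path to a TSV file.
#' @param transpose If `TRUE`, the file has samples in rows.
#' @return Numeric matrix, genes in rows, with gene/sample dimnames.
#' @export
read_expression <- function(path, transpose = FALSE) {
  if (!file.exists(path)) stop_fs("file not found: %s", path)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2) stop_fs("malformed expression file (need id column plus >= 1 sample): %s", path)
  if (nrow(raw) == 0) stop_fs("empty expression file: %s", path)
  ids <- split_composite_ids(raw[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop_fs("duplicate %s IDs in %s: %s", if (transpose) "sample" else "gene",
            path, paste(dup, collapse = ", "))
  }
  vals <- matrix(NA_real_, nrow(raw), ncol(raw) - 1L,
                 dimnames = list(ids, colnames(raw)[-1]))
  for (j in seq_len(ncol(vals))) {
    col <- raw[[j + 1L]]
    x <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(x) & !is.na(col))
    if (length(bad) > 0) {
      stop_fs("non-numeric value '%s' at row %d (%s), column %s",
              col[bad[1]], bad[1], ids[bad[1]], colnames(vals)[j])
    }
    if (anyNA(x)) {
      bad <- which(is.na(x))[1]
      stop_fs("missing value at row %d (%s), column %s", bad, ids[bad], colnames(vals)[j])
    }
    neg <- which(x < 0)
    if (length(neg) > 0) {
      stop_fs("negative value %s at row %d (%s), column %s",
              format(x[neg[1]]), neg[1], ids[neg[1]], colnames(vals)[j])
    }
    vals[, j] <- x
  }
  if (transpose) vals <- t(vals)
  assert_expression_matrix(vals)
  vals
}

#' Write an expression matrix as genes-in-rows TSV
#'
#' @param expr Numeric genes x samples matrix with dimnames.
#' @param path Output path.
#' @param id_column Name of the first (gene identifier) column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, id_column = "gene_id") {
  assert_expression_matrix(expr)
  out <- tibble::as_tibble(expr, rownames = id_column)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

split_composite_ids <- function(ids) {
  sub("\\|.*$", "", ids)
}
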