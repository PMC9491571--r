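# internal helpers shared across modules

stop_fs <- function(msg, ..., class = "fusionscreen_error") {
  rlang::abort(sprintf(msg, ...), class = class)
}

check_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != floor(x)) {
    stop_fs("`%s` must be a single integer >= %d, got %s", name, min,
            paste(format(x), collapse = ","))
  }
  as.integer(x)
}

check_prob <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x > 1) {
    stop_fs("`%s` must be a single value in [0, 1]", name)
  }
  as.numeric(x)
}

#' @noRd
assert_expression_matrix <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop_fs("expression must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop_fs("expression matrix needs gene row names and sample column names")
  }
  if (anyDuplicated(rownames(expr))) {
    stop_fs("duplicate gene IDs: %s",
            paste(unique(rownames(expr)[duplicated(rownames(expr))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(expr))) {
    stop_fs("duplicate sample IDs: %s",
            paste(unique(colnames(expr)[duplicated(colnames(expr))]), collapse = ", "))
  }
  if (any(!is.finite(expr))) stop_fs("expression values must all be finite")
  if (any(expr < 0)) stop_fs("expression values must be non-negative")
  invisible(expr)
}

# Derive a stage seed from a master seed; keeps results < 2^31 and
# decorrelates stages without consuming the global RNG stream.
derive_seed <- function(seed, stage) {
  seed <- check_count(seed, "seed")
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

# median of |R| and signed R direction label
direction_of <- function(med_signed) {
  dplyr::case_when(med_signed > 0 ~ "up", med_signed < 0 ~ "down", TRUE ~ "flat")
}
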