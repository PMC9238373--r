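# internal helpers shared across modules

# counts must be samples x features with both dimnames set
check_count_table <- function(table, arg = "table") {
  if (!is.matrix(table) || !is.numeric(table))
    stop(sprintf("`%s` must be a numeric matrix (samples x features)", arg), call. = FALSE)
  if (is.null(rownames(table)) || is.null(colnames(table)))
    stop(sprintf("`%s` must have sample rownames and feature colnames", arg), call. = FALSE)
  if (anyDuplicated(rownames(table)))
    stop("duplicate sample IDs in count table", call. = FALSE)
  if (anyDuplicated(colnames(table)))
    stop("duplicate feature IDs in count table", call. = FALSE)
  if (any(is.na(table)))
    stop(sprintf("`%s` contains missing values", arg), call. = FALSE)
  if (any(table < 0))
    stop("negative counts are not allowed", call. = FALSE)
  invisible(table)
}

# deterministic sub-stream seeds derived from one user seed, kept inside
# 32-bit integer range
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(k)) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
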