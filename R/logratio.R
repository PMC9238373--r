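#' Log-ratio of counts aggregated under two tree nodes
#'
#' For each sample, the natural log of (sum of counts over the tips under the
#' numerator node) / (sum over the tips under the denominator node). The two
#' tip sets must be disjoint — on a tree this is exactly the requirement that
#' neither node is an ancestor of the other; overlapping numerator and
#' denominator sums would be misleading and are rejected. Samples with a zero
#' sum on either side are dropped and reported rather than pseudocounted:
#' choosing dense clades, not imputation, is how sample drop-out is avoided.
#'
#' @param table Samples x features count matrix (features are tree tips).
#' @param tree Rooted `ape::phylo` with node labels (see [parse_newick()]).
#' @param num,den Numerator / denominator node IDs (tips or internal nodes).
#' @return Tibble with `sample`, `log_ratio`, `numerator_sum`,
#'   `denominator_sum` for retained samples; attributes `dropped_samples`,
#'   `numerator_tips`, `denominator_tips`, `numerator`, `denominator`.
#' @export
node_log_ratio <- function(table, tree, num, den) {
  check_count_table(table)
  tree <- label_internal_nodes(tree)
  nt <- tips_under(tree, num)
  dt <- tips_under(tree, den)
  ov <- intersect(nt, dt)
  if (length(ov))
    stop("overlapping features between numerator and denominator: ",
         paste(utils::head(ov, 5), collapse = ", "), call. = FALSE)
  num_sum <- aggregate_tips(table, nt)
  den_sum <- aggregate_tips(table, dt)
  ok <- num_sum > 0 & den_sum > 0
  if (!any(ok)) stop("all samples dropped (zero sums)", call. = FALSE)
  out <- tibble::tibble(sample = rownames(table)[ok],
                        log_ratio = unname(log(num_sum[ok] / den_sum[ok])),
                        numerator_sum = unname(num_sum[ok]),
                        denominator_sum = unname(den_sum[ok]))
  attr(out, "dropped_samples") <- rownames(table)[!ok]
  attr(out, "numerator") <- num
  attr(out, "denominator") <- den
  attr(out, "numerator_tips") <- nt
  attr(out, "denominator_tips") <- dt
  out
}

aggregate_tips <- function(table, tips) {
  present <- intersect(tips, colnames(table))
  if (!length(present)) return(stats::setNames(rep(0, nrow(table)), rownames(table)))
  rowSums(table[, present, drop = FALSE])
}

#' Lowest-common-ancestor lineage of a node
#'
#' Annotates an internal node with the deepest taxonomy shared by all its
#' descendant tips: lineages are semicolon-delimited ranked strings
#' (Greengenes style, e.g. `"k__Bacteria;p__Firmicutes;o__..."`) and the
#' result is the longest common rank prefix. Tips without a lineage are
#' skipped with a warning.
#'
#' @param tree Rooted `ape::phylo` with node labels.
#' @param node_id Node to annotate.
#' @param taxonomy Tip-to-lineage map: a named character vector, or a
#'   two-column data frame (tip, lineage).
#' @return The common lineage string (empty when the tips share no rank).
#' @export
lca_annotate <- function(tree, node_id, taxonomy) {
  if (is.data.frame(taxonomy))
    taxonomy <- stats::setNames(as.character(taxonomy[[2]]), as.character(taxonomy[[1]]))
  tips <- tips_under(tree, node_id)
  have <- tips %in% names(taxonomy)
  if (!all(have)) {
    warning("no lineage for tip(s): ",
            paste(utils::head(tips[!have], 5), collapse = ", "))
    tips <- tips[have]
  }
  if (!length(tips)) stop("no descendant tip has a lineage", call. = FALSE)
  ranks <- lapply(taxonomy[tips], function(s) trimws(strsplit(s, ";", fixed = TRUE)[[1]]))
  depth <- min(lengths(ranks))
  common <- character(0)
  for (i in seq_len(depth)) {
    lev <- vapply(ranks, `[`, "", i)
    if (length(unique(lev)) > 1) break
    common <- c(common, lev[[1]])
  }
  paste(common, collapse = ";")
}
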