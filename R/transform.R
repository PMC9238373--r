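#' Masked log-value matrix
#'
#' Container for (robust) log-ratio transformed values where zeros in the
#' underlying counts are treated as missing rather than imputed: `values` is
#' defined exactly where `mask` is `TRUE` and `NA` elsewhere.
#'
#' @param values Numeric samples x columns matrix.
#' @param mask Logical matrix of the same shape; `TRUE` = observed.
#' @return An object of class `masked_log` (a list with `values` and `mask`).
#' @export
masked_log <- function(values, mask) {
  stopifnot(is.matrix(values), is.logical(mask), all(dim(values) == dim(mask)))
  if (any(is.na(values[mask])))
    stop("values must be defined wherever mask is TRUE", call. = FALSE)
  values[!mask] <- NA_real_
  structure(list(values = values, mask = mask), class = "masked_log")
}

#' @export
print.masked_log <- function(x, ...) {
  cat(sprintf("<masked_log> %d samples x %d columns, %.1f%% observed\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$mask)))
  invisible(x)
}

#' Compositional closure
#'
#' Scales each sample (row) to proportions summing to one. Zeros are
#' preserved; a sample with no positive entry is an error.
#'
#' @param matrix Nonnegative samples x columns matrix.
#' @return Row-closed proportion matrix of the same shape.
#' @export
closure <- function(matrix) {
  if (any(matrix < 0, na.rm = TRUE)) stop("negative values", call. = FALSE)
  rs <- rowSums(matrix)
  if (any(rs <= 0)) {
    bad <- rownames(matrix)[rs <= 0] %||% which(rs <= 0)
    stop("empty sample: ", paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  sweep(matrix, 1, rs, "/")
}

#' Robust centered log-ratio transform
#'
#' The clr transform restricted to observed (positive) entries: for each
#' sample, observed values become `log(x) - mean(log(x) over observed entries)`
#' and zeros are masked out rather than imputed. On a dense matrix this equals
#' the classic clr. Natural logarithms throughout.
#'
#' @param matrix Nonnegative samples x columns matrix; each sample needs at
#'   least one positive entry.
#' @return A [masked_log()] object.
#' @examples
#' rclr(matrix(c(1, 4, 0, 16), 1, dimnames = list("s", paste0("f", 1:4))))
#' @export
rclr <- function(matrix) {
  if (any(matrix < 0, na.rm = TRUE)) stop("negative values", call. = FALSE)
  mask <- matrix > 0
  if (any(rowSums(mask) == 0)) stop("sample with no observed entries", call. = FALSE)
  lg <- ifelse(mask, log(matrix), NA_real_)
  ctr <- rowSums(lg, na.rm = TRUE) / rowSums(mask)
  masked_log(lg - ctr, mask)
}

#' Iterative double centering of a masked matrix
#'
#' Alternately removes row means and column means computed over observed
#' entries only, until the largest absolute observed row or column mean falls
#' below `tol`. On dense input a single pass per side suffices; on masked
#' input the two centerings interact and the iteration converges linearly.
#' Masked entries are untouched.
#'
#' @param m A [masked_log()] object (or plain numeric matrix, taken as dense).
#' @param tol Convergence tolerance on the observed row/column means.
#' @param max_iter Iteration cap; non-convergence warns and returns the best
#'   iterate.
#' @return A [masked_log()] object with observed row and column means ~ 0.
#' @export
double_center <- function(m, tol = 1e-8, max_iter = 500) {
  if (is.matrix(m)) m <- masked_log(m, !is.na(m))
  v <- m$values
  msk <- m$mask
  nr <- rowSums(msk)
  nc <- colSums(msk)
  if (any(nr == 0) || any(nc == 0))
    stop("mask has an empty row or column", call. = FALSE)
  for (it in seq_len(max_iter)) {
    v <- v - rowSums(v, na.rm = TRUE) / nr
    v <- sweep(v, 2, colSums(v, na.rm = TRUE) / nc, "-")
    dev <- max(abs(rowSums(v, na.rm = TRUE) / nr), abs(colSums(v, na.rm = TRUE) / nc))
    if (dev < tol) break
  }
  if (dev >= tol)
    warning(sprintf("double_center did not reach tol %g in %d iterations (dev %g)",
                    tol, max_iter, dev))
  masked_log(ifelse(msk, v, NA_real_), msk)
}

#' Phylogenetic robust centered log-ratio transform
#'
#' Expands the count table to all non-root tree nodes ([expand_table()]),
#' closes each sample, weights every node column by its branch length, and
#' applies [rclr()] to the weighted matrix. A node is observed in a sample iff
#' at least one of its descendant tips has a positive count there. With a
#' star tree of equal branch lengths this reduces exactly to [rclr()] on the
#' tips.
#'
#' @inheritParams expand_table
#' @return A list with `masked` (the [masked_log()] transform), `expanded`
#'   (node count matrix), `weights` (branch lengths) and `tree`.
#' @export
phylo_rclr <- function(table, tree) {
  ex <- expand_table(table, tree)
  p <- closure(ex$counts)
  w <- sweep(p, 2, ex$weights, "*")
  list(masked = rclr(w), expanded = ex$counts, weights = ex$weights, tree = ex$tree)
}
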