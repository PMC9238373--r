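#' Masked low-rank factorization by alternating least squares
#'
#' Fits `Y ~ U diag(d) V'` minimizing squared error over the observed entries
#' of a masked matrix. Row and column factors are updated by exact least
#' squares in alternation (the objective is monotone nonincreasing), starting
#' from a seeded uniform(-0.5, 0.5)/sqrt(rank) initialization, and the
#' converged factors are orthonormalized through a final small SVD so that
#' `d` is nonincreasing and `U`, `V` have orthonormal columns.
#'
#' @param m A [masked_log()] object or numeric matrix (NAs = masked).
#' @param rank Target rank, at most `min(dim)`.
#' @param max_iter Iteration cap.
#' @param tol Relative change in the observed-entry objective at which to stop.
#' @param seed Integer seed for the initialization.
#' @return List with `u` (rows x rank), `d` (length-rank, nonincreasing),
#'   `v` (cols x rank), `objective` (per-iteration trace) and `iterations`.
#' @examples
#' f <- masked_factorize(matrix(c(1, 2, 2, NA), 2), rank = 1, seed = 1)
#' (f$u %*% diag(f$d, 1) %*% t(f$v))[2, 2] # completed entry ~ 4
#' @export
masked_factorize <- function(m, rank, max_iter = 1000, tol = 1e-8, seed = 1) {
  if (is.matrix(m)) m <- masked_log(m, !is.na(m))
  msk <- m$mask
  Y <- ifelse(msk, m$values, 0)
  n <- nrow(Y)
  p <- ncol(Y)
  rank <- as.integer(rank)
  if (rank < 1 || rank > min(n, p))
    stop(sprintf("rank must be in [1, %d]", min(n, p)), call. = FALSE)
  if (any(rowSums(msk) == 0) || any(colSums(msk) == 0))
    stop("mask has an empty row or column", call. = FALSE)
  M <- msk * 1
  V <- withr::with_seed(as.integer(seed),
                        matrix(stats::runif(p * rank, -0.5, 0.5) / sqrt(rank), p, rank))
  U <- matrix(0, n, rank)
  obj <- numeric(0)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    U <- als_solve(Y, M, V)
    V <- als_solve(t(Y), t(M), U)
    res <- M * (Y - U %*% t(V))
    o <- sum(res * res)
    obj <- c(obj, o)
    if (is.finite(prev) && abs(prev - o) <= tol * max(prev, .Machine$double.eps)) break
    prev <- o
  }
  qu <- qr(U)
  qv <- qr(V)
  sv <- svd(qr.R(qu) %*% t(qr.R(qv)))
  U <- qr.Q(qu) %*% sv$u
  V <- qr.Q(qv) %*% sv$v
  # deterministic sign: largest-magnitude loading of each axis positive
  for (k in seq_len(rank)) {
    s <- sign(V[which.max(abs(V[, k])), k])
    if (s < 0) { V[, k] <- -V[, k]; U[, k] <- -U[, k] }
  }
  rownames(U) <- rownames(Y)
  rownames(V) <- colnames(Y)
  list(u = U, d = sv$d, v = V, objective = obj, iterations = length(obj))
}

# rows of X solved independently: for each row i minimize
# || M[i,] * (X[i,] - b %*% t(F)) ||^2 over b
als_solve <- function(X, M, Fm) {
  r <- ncol(Fm)
  n <- nrow(X)
  # per-row r x r normal matrices, assembled by matrix products
  G <- array(0, c(n, r, r))
  for (k in seq_len(r)) for (l in k:r) {
    g <- M %*% (Fm[, k] * Fm[, l])
    G[, k, l] <- g
    G[, l, k] <- g
  }
  B <- (M * X) %*% Fm
  out <- matrix(0, n, r)
  for (i in seq_len(n)) {
    A <- G[i, , , drop = TRUE]
    if (r == 1) A <- matrix(A, 1, 1)
    out[i, ] <- tryCatch(solve(A, B[i, ]),
                         error = function(e) solve(A + diag(1e-10 * (1 + max(diag(A))), r), B[i, ]))
  }
  out
}

new_ordination <- function(d, prop, scores, loadings, extra = list()) {
  structure(c(list(eigenvalues = d, proportion_explained = prop,
                   sample_scores = scores, feature_loadings = loadings,
                   rank = length(d)), extra),
            class = "treecoda_ordination")
}

#' @export
print.treecoda_ordination <- function(x, ...) {
  cat(sprintf("<treecoda_ordination> rank %d: %d samples, %d features/nodes\n",
              x$rank, nrow(x$sample_scores), nrow(x$feature_loadings)))
  cat("  proportion explained:", paste(sprintf("%.3f", x$proportion_explained), collapse = " "), "\n")
  invisible(x)
}

#' (Phylogenetic) robust principal component analysis
#'
#' Cross-sectional ordination of a sparse compositional count table. The
#' table is transformed with [rclr()] (or [phylo_rclr()] when a tree is
#' supplied, in which case internal tree nodes join the feature space),
#' doubly centered over observed entries, and factorized with
#' [masked_factorize()]. Sample scores are `U diag(d)`; feature/node loadings
#' are `V`; sample distances are Euclidean distances between score rows (the
#' low-rank Aitchison distance convention).
#'
#' @param table Samples x features count matrix.
#' @param tree Optional rooted `ape::phylo` covering the features; `NULL`
#'   runs plain (non-phylogenetic) RPCA.
#' @param rank Number of components (default 3).
#' @param min_feature_count Drop features whose total count is not greater
#'   than this (see [filter_features()]); 0 drops only all-zero features.
#' @param seed Integer seed (factorization initialization).
#' @param max_iter,tol Passed to [masked_factorize()].
#' @return List with `ordination` (a `treecoda_ordination`) and `distance`
#'   (labeled symmetric matrix).
#' @export
rpca <- function(table, tree = NULL, rank = 3, min_feature_count = 0, seed = 1,
                 max_iter = 1000, tol = 1e-8) {
  check_count_table(table)
  if (min_feature_count > 0)
    table <- filter_features(table, min_feature_count)
  zero <- colSums(table) == 0
  if (any(zero)) {
    message(sum(zero), " all-zero feature(s) dropped")
    table <- table[, !zero, drop = FALSE]
  }
  if (ncol(table) < 2) stop("need at least 2 features", call. = FALSE)
  if (nrow(table) < rank + 1) {
    rank <- max(1L, nrow(table) - 1L)
    warning("fewer samples than rank + 1; rank clamped to ", rank)
  }
  if (is.null(tree)) {
    ml <- rclr(table)
  } else {
    ml <- phylo_rclr(table, tree)$masked
  }
  dc <- double_center(ml)
  f <- masked_factorize(dc, rank = rank, max_iter = max_iter, tol = tol, seed = seed)
  scores <- f$u %*% diag(f$d, length(f$d))
  dimnames(scores) <- list(rownames(table), paste0("PC", seq_along(f$d)))
  loadings <- f$v
  colnames(loadings) <- paste0("PC", seq_along(f$d))
  denom <- max(sum(dc$values[dc$mask]^2), sum(f$d^2))
  ord <- new_ordination(f$d, f$d^2 / denom, scores, loadings,
                        extra = list(phylogenetic = !is.null(tree)))
  D <- as.matrix(stats::dist(scores))
  list(ordination = ord, distance = D)
}

#' Rank feature/node loadings along an ordination axis
#'
#' @param ord A `treecoda_ordination`.
#' @param axis Component index (1-based).
#' @param top_k Number of most positive and most negative loadings to return.
#' @return A tibble with `node_id`, `loading`, `direction`
#'   ("positive"/"negative"), sorted by signed loading within direction.
#' @export
rank_loadings <- function(ord, axis = 1, top_k = 10) {
  if (!inherits(ord, "treecoda_ordination")) stop("not an ordination", call. = FALSE)
  if (axis < 1 || axis > ord$rank) stop("axis out of range", call. = FALSE)
  v <- ord$feature_loadings[, axis]
  n <- length(v)
  if (top_k > n) {
    warning("top_k larger than node count; clamped to ", n)
    top_k <- n
  }
  o <- order(v, decreasing = TRUE)
  pos <- o[seq_len(top_k)]
  neg <- rev(o)[seq_len(top_k)]
  tibble::tibble(
    node_id = c(names(v)[pos], names(v)[neg]),
    loading = unname(c(v[pos], v[neg])),
    direction = rep(c("positive", "negative"), each = top_k))
}
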