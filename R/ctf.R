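#' (Phylogenetic) compositional tensor factorization
#'
#' Repeated-measures ordination. Samples are mapped to (subject, state) cells
#' of a subject x feature/node x state tensor of (phylo-)rclr values; cells
#' without a sample, and zero counts, are masked. The tensor is fitted with a
#' masked CP (canonical polyadic) decomposition by alternating least squares
#' with a seeded initialization. States are unordered categories; the method
#' knows which measurements share a subject but not their temporal order.
#'
#' Each state slice is doubly centered over its observed entries before
#' fitting, so that with a single state the model reduces to [rpca()]
#' (subject scores agree up to rotation).
#'
#' @param table Samples x features count matrix.
#' @param tree Optional rooted `ape::phylo`; `NULL` gives plain CTF.
#' @param metadata Data frame of per-sample metadata: either rownames are
#'   sample IDs or the first column holds them.
#' @param subject_col,state_col Metadata column names for the subject and the
#'   repeated-measure state (e.g. timepoint).
#' @param rank Number of components (default 3).
#' @param seed Integer seed for the initialization.
#' @param max_iter,tol ALS controls (relative objective change).
#' @return List with `ordination` (subject scores in `sample_scores`, feature
#'   loadings, plus `state_scores`), `distance` (subject x subject), and
#'   `state_loadings` (tibble of per-state component scores).
#' @export
ctf <- function(table, tree = NULL, metadata, subject_col, state_col,
                rank = 3, seed = 1, max_iter = 500, tol = 1e-10) {
  check_count_table(table)
  md <- normalize_metadata(metadata)
  for (cl in c(subject_col, state_col))
    if (!cl %in% colnames(md)) stop("metadata column not found: ", cl, call. = FALSE)
  missing <- setdiff(rownames(table), rownames(md))
  if (length(missing))
    stop("samples without metadata: ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  md <- md[rownames(table), , drop = FALSE]
  subj <- as.character(md[[subject_col]])
  state <- as.character(md[[state_col]])
  key <- paste(subj, state, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicated (subject, state) pair: ",
         gsub("\r", " / ", d), call. = FALSE)
  }
  subjects <- unique(subj)
  states <- unique(state)
  if (length(subjects) < 2) stop("need at least 2 subjects", call. = FALSE)
  zero <- colSums(table) == 0
  if (any(zero)) table <- table[, !zero, drop = FALSE]
  ml <- if (is.null(tree)) rclr(table) else phylo_rclr(table, tree)$masked
  nodes <- colnames(ml$values)
  rank <- as.integer(rank)
  if (rank > min(length(subjects), length(nodes)))
    stop("rank too large for subject/feature dimensions", call. = FALSE)

  # per-state subject x node slices, double centered over observed entries
  slices <- lapply(states, function(st) {
    Y <- matrix(NA_real_, length(subjects), length(nodes),
                dimnames = list(subjects, nodes))
    rows <- which(state == st)
    Y[subj[rows], ] <- ml$values[rows, , drop = FALSE]
    msk <- !is.na(Y)
    keep_r <- rowSums(msk) > 0
    Yc <- Y
    if (any(colSums(msk[keep_r, , drop = FALSE]) == 0)) {
      # nodes unobserved in this state stay masked; center over the rest
      obs_c <- colSums(msk) > 0
      dcd <- double_center(masked_log(Y[keep_r, obs_c, drop = FALSE],
                                      msk[keep_r, obs_c, drop = FALSE]))
      Yc[keep_r, obs_c] <- dcd$values
    } else {
      dcd <- double_center(masked_log(Y[keep_r, , drop = FALSE],
                                      msk[keep_r, , drop = FALSE]))
      Yc[keep_r, ] <- dcd$values
    }
    list(values = ifelse(msk, Yc, 0), mask = msk * 1)
  })

  fit <- cp_als(slices, rank, max_iter = max_iter, tol = tol, seed = seed)
  A <- fit$A; B <- fit$B; Cm <- fit$C; lam <- fit$lambda
  # CP factors are defined only up to an oblique mixing; the subject biplot
  # is taken as the SVD of the fitted tensor averaged over the state mode,
  # which is invariant to that indeterminacy and reduces to the matrix
  # factorization when there is a single state
  Fmean <- A %*% diag(lam * colMeans(Cm), rank) %*% t(B)
  sv <- svd(Fmean, nu = rank, nv = rank)
  lam <- sv$d[seq_len(rank)]
  scores <- sv$u %*% diag(lam, rank)
  B <- sv$v
  for (k in seq_len(rank)) {
    s <- sign(B[which.max(abs(B[, k])), k])
    if (s < 0) { B[, k] <- -B[, k]; scores[, k] <- -scores[, k] }
  }
  dimnames(scores) <- list(subjects, paste0("PC", seq_len(rank)))
  rownames(B) <- nodes
  colnames(B) <- paste0("PC", seq_len(rank))
  dimnames(Cm) <- list(states, paste0("PC", seq_len(rank)))
  obs2 <- sum(vapply(slices, function(s) sum((s$values * s$mask)^2), 0))
  denom <- max(obs2, sum(lam^2))
  ord <- new_ordination(lam, lam^2 / denom, scores, B,
                        extra = list(state_scores = Cm,
                                     phylogenetic = !is.null(tree),
                                     subject_col = subject_col,
                                     state_col = state_col))
  D <- as.matrix(stats::dist(scores))
  sl <- tibble::tibble(
    state = rep(states, rank),
    component = rep(paste0("PC", seq_len(rank)), each = length(states)),
    score = as.vector(Cm))
  list(ordination = ord, distance = D, state_loadings = sl)
}

# masked CP-ALS over a list of (values, mask) subject x node slices
cp_als <- function(slices, rank, max_iter, tol, seed) {
  I <- nrow(slices[[1]]$values)
  J <- ncol(slices[[1]]$values)
  Tn <- length(slices)
  A <- withr::with_seed(as.integer(seed), {
    list(matrix(stats::runif(I * rank, -0.5, 0.5) / sqrt(rank), I, rank),
         matrix(stats::runif(J * rank, -0.5, 0.5) / sqrt(rank), J, rank),
         matrix(stats::runif(Tn * rank, -0.5, 0.5) / sqrt(rank), Tn, rank))
  })
  B <- A[[2]]; Cm <- A[[3]]; A <- A[[1]]
  prev <- Inf
  obj <- numeric(0)
  for (it in seq_len(max_iter)) {
    A <- cp_update_mode(slices, B, Cm, transpose = FALSE)
    B <- cp_update_mode(slices, A, Cm, transpose = TRUE)
    Cm <- cp_update_state(slices, A, B)
    o <- 0
    for (t in seq_len(Tn)) {
      R <- slices[[t]]$mask * (slices[[t]]$values - (A %*% diag(Cm[t, ], rank)) %*% t(B))
      o <- o + sum(R * R)
    }
    obj <- c(obj, o)
    if (is.finite(prev) && abs(prev - o) <= tol * max(prev, .Machine$double.eps)) break
    prev <- o
  }
  # normalize and order components
  na <- sqrt(colSums(A^2)); nb <- sqrt(colSums(B^2)); nc <- sqrt(colSums(Cm^2))
  na[na == 0] <- 1; nb[nb == 0] <- 1; nc[nc == 0] <- 1
  A <- sweep(A, 2, na, "/"); B <- sweep(B, 2, nb, "/"); Cm <- sweep(Cm, 2, nc, "/")
  lam <- na * nb * nc
  ord <- order(lam, decreasing = TRUE)
  A <- A[, ord, drop = FALSE]; B <- B[, ord, drop = FALSE]
  Cm <- Cm[, ord, drop = FALSE]; lam <- lam[ord]
  for (k in seq_len(rank)) {
    s <- sign(B[which.max(abs(B[, k])), k])
    if (s < 0) { B[, k] <- -B[, k]; A[, k] <- -A[, k] }
    s <- sign(Cm[which.max(abs(Cm[, k])), k])
    if (s < 0) { Cm[, k] <- -Cm[, k]; A[, k] <- -A[, k] }
  }
  list(A = A, B = B, C = Cm, lambda = lam, objective = obj, iterations = length(obj))
}

# update subject factors (transpose = FALSE) or feature factors (TRUE):
# for each row i solve sum_t (c_t c_t') o G_t[i] b = rhs
cp_update_mode <- function(slices, Fother, Cm, transpose) {
  r <- ncol(Fother)
  n <- if (transpose) ncol(slices[[1]]$values) else nrow(slices[[1]]$values)
  G <- array(0, c(n, r, r))
  RHS <- matrix(0, n, r)
  for (t in seq_along(slices)) {
    M <- slices[[t]]$mask
    Y <- slices[[t]]$values * M
    if (transpose) { M <- t(M); Y <- t(Y) }
    ct <- Cm[t, ]
    cc <- tcrossprod(ct)
    for (k in seq_len(r)) for (l in k:r) {
      g <- (M %*% (Fother[, k] * Fother[, l])) * cc[k, l]
      G[, k, l] <- G[, k, l] + g
      if (l > k) G[, l, k] <- G[, l, k] + g
    }
    RHS <- RHS + sweep(Y %*% Fother, 2, ct, "*")
  }
  out <- matrix(0, n, r)
  for (i in seq_len(n)) {
    Am <- G[i, , , drop = TRUE]
    if (r == 1) Am <- matrix(Am, 1, 1)
    out[i, ] <- tryCatch(solve(Am, RHS[i, ]),
                         error = function(e) solve(Am + diag(1e-10 * (1 + max(diag(Am))), r), RHS[i, ]))
  }
  out
}

cp_update_state <- function(slices, A, B) {
  r <- ncol(A)
  Tn <- length(slices)
  Cm <- matrix(0, Tn, r)
  for (t in seq_len(Tn)) {
    M <- slices[[t]]$mask
    Y <- slices[[t]]$values * M
    N <- matrix(0, r, r)
    rhs <- numeric(r)
    for (k in seq_len(r)) {
      for (l in k:r) {
        N[k, l] <- N[l, k] <- sum((A[, k] * A[, l]) * (M %*% (B[, k] * B[, l])))
      }
      rhs[k] <- sum(A[, k] * (Y %*% B[, k]))
    }
    Cm[t, ] <- tryCatch(solve(N, rhs),
                        error = function(e) solve(N + diag(1e-10 * (1 + max(diag(N))), r), rhs))
  }
  Cm
}

# metadata: rownames = sample IDs, or first column holds them
normalize_metadata <- function(metadata) {
  md <- as.data.frame(metadata)
  if (is.null(rownames(md)) ||
      identical(rownames(md), as.character(seq_len(nrow(md))))) {
    ids <- as.character(md[[1]])
    if (anyDuplicated(ids)) stop("duplicate sample IDs in metadata", call. = FALSE)
    rownames(md) <- ids
    md <- md[, -1, drop = FALSE]
  }
  md
}
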