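#' PERMANOVA pseudo-F on a distance matrix
#'
#' One-way permutational multivariate analysis of variance: the pseudo-F is
#' computed from among- and within-group sums of squared distances
#' (Gower-centered), and its null distribution from seeded label
#' permutations. The p-value uses the add-one estimator
#' `(1 + #\{F_perm >= F_obs\}) / (1 + permutations)`. With Euclidean
#' distances on 1-D data this equals the classical one-way ANOVA F.
#'
#' @param d Distance matrix (`dist` or labeled symmetric matrix).
#' @param grouping Group label per sample: a named vector (names = sample
#'   IDs) or a vector aligned to the distance labels.
#' @param permutations Number of label permutations (0 skips the test and
#'   returns `p_value = NA`).
#' @param seed Integer seed for the permutations.
#' @return One-row tibble: `F_statistic`, `p_value`, `df_between`,
#'   `df_within`, `permutations`.
#' @export
permanova <- function(d, grouping, permutations = 999, seed = 1) {
  D <- as.matrix(d)
  n <- nrow(D)
  ids <- rownames(D) %||% as.character(seq_len(n))
  if (!is.null(names(grouping))) {
    miss <- setdiff(ids, names(grouping))
    if (length(miss))
      stop("unlabeled samples: ", paste(utils::head(miss, 5), collapse = ", "),
           call. = FALSE)
    grouping <- grouping[ids]
  } else if (length(grouping) != n) {
    stop("grouping must cover all samples", call. = FALSE)
  }
  g <- as.factor(as.character(grouping))
  a <- nlevels(g)
  if (a < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) < 2)) stop("every group needs at least 2 samples", call. = FALSE)
  D2 <- D^2
  ss_total <- sum(D2) / (2 * n)
  fstat_of <- function(gi) {
    ssw <- 0
    for (lv in levels(gi)) {
      idx <- gi == lv
      ssw <- ssw + sum(D2[idx, idx]) / (2 * sum(idx))
    }
    ((ss_total - ssw) / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- fstat_of(g)
  p <- NA_real_
  if (permutations > 0) {
    nlev <- table(g)
    f_perm <- withr::with_seed(as.integer(seed), {
      # vectorized: binary indicators per group across all permutations
      perms <- replicate(permutations, sample.int(n))
      vapply(seq_len(permutations), function(b) {
        gi <- g[perms[, b]]
        ssw <- 0
        for (lv in levels(g)) {
          idx <- gi == lv
          ssw <- ssw + sum(D2[idx, idx]) / (2 * nlev[[lv]])
        }
        ((ss_total - ssw) / (a - 1)) / (ssw / (n - a))
      }, 0)
    })
    p <- (1 + sum(f_perm >= f_obs)) / (1 + permutations)
  }
  tibble::tibble(F_statistic = f_obs, p_value = p,
                 df_between = a - 1L, df_within = n - a,
                 permutations = as.integer(permutations))
}

#' KNN classification accuracy of ordination scores
#'
#' Repeated stratified random-split cross-validation of a k-nearest-neighbor
#' classifier on the first `min(r, 3)` ordination components. Each fold draws
#' a seeded stratified split at `split` train fraction; test samples receive
#' per-class vote fractions from their `k` nearest training points, scored by
#' one-vs-rest average precision (PR-AUC) and rank-based ROC-AUC,
#' macro-averaged over classes and then averaged over folds.
#'
#' @param scores Samples x components numeric matrix (rownames = sample IDs).
#' @param labels Class label per sample (named vector or aligned).
#' @param k Number of neighbors (clamped, with a warning, to the smallest
#'   training class when larger).
#' @param folds Number of repeated splits.
#' @param split Train fraction in (0, 1).
#' @param seed Integer seed.
#' @return One-row tibble: `pr_auc`, `roc_auc`, `k`, `folds`, `split`.
#' @export
knn_cv <- function(scores, labels, k = 3, folds = 10, split = 0.5, seed = 1) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  ids <- rownames(scores) %||% as.character(seq_len(n))
  if (!is.null(names(labels))) labels <- labels[ids]
  if (length(labels) != n) stop("labels must cover all samples", call. = FALSE)
  y <- as.factor(as.character(labels))
  if (nlevels(y) < 2) stop("need at least 2 classes", call. = FALSE)
  if (split <= 0 || split >= 1) stop("split must be in (0, 1)", call. = FALSE)
  X <- scores[, seq_len(min(ncol(scores), 3)), drop = FALSE]
  res <- withr::with_seed(as.integer(seed), {
    pr <- roc <- numeric(folds)
    for (f in seq_len(folds)) {
      train <- unlist(lapply(levels(y), function(lv) {
        idx <- which(y == lv)
        nt <- max(1, min(length(idx) - 1, round(split * length(idx))))
        sample(idx, nt)
      }))
      test <- setdiff(seq_len(n), train)
      kf <- min(k, min(table(y[train])))
      if (kf < k)
        warning("k larger than smallest training class; clamped to ", kf)
      votes <- knn_votes(X[train, , drop = FALSE], y[train], X[test, , drop = FALSE], kf)
      pcl <- rcl <- numeric(0)
      for (lv in levels(y)) {
        truth <- as.integer(y[test] == lv)
        if (all(truth == 0) || all(truth == 1)) next
        pcl <- c(pcl, average_precision(truth, votes[, lv]))
        rcl <- c(rcl, rank_auc(truth, votes[, lv]))
      }
      pr[f] <- mean(pcl)
      roc[f] <- mean(rcl)
    }
    c(pr = mean(pr), roc = mean(roc))
  })
  tibble::tibble(pr_auc = res[["pr"]], roc_auc = res[["roc"]],
                 k = as.integer(k), folds = as.integer(folds), split = split)
}

# per-class vote fractions of the k nearest training rows
knn_votes <- function(Xtr, ytr, Xte, k) {
  lv <- levels(ytr)
  d2 <- outer(rowSums(Xte^2), rowSums(Xtr^2), "+") - 2 * Xte %*% t(Xtr)
  votes <- matrix(0, nrow(Xte), length(lv), dimnames = list(NULL, lv))
  for (i in seq_len(nrow(Xte))) {
    nb <- ytr[order(d2[i, ])[seq_len(k)]]
    votes[i, ] <- tabulate(nb, nbins = length(lv)) / k
  }
  votes
}

# average precision (step-wise PR-AUC) with proper tie handling
average_precision <- function(truth, score) {
  o <- order(score, decreasing = TRUE)
  truth <- truth[o]
  score <- score[o]
  tp <- cumsum(truth)
  fp <- cumsum(1 - truth)
  keep <- c(which(diff(score) != 0), length(score))
  prec <- tp[keep] / (tp[keep] + fp[keep])
  rec <- tp[keep] / sum(truth)
  sum(diff(c(0, rec)) * prec)
}

# ROC-AUC via the rank (Mann-Whitney) statistic, mid-ranks for ties
rank_auc <- function(truth, score) {
  np <- sum(truth == 1)
  nn <- sum(truth == 0)
  r <- rank(score)
  (sum(r[truth == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Benchmark (phylo-)RPCA over a simulation grid
#'
#' For every combination of depth, tip-shuffle proportion and replicate seed,
#' simulates a block data set ([simulate_blocks()]), runs the requested
#' methods, and evaluates each sample distance matrix with [permanova()] and
#' each ordination with [knn_cv()] against the true block labels.
#'
#' @param depths Numeric vector of sequencing depths.
#' @param shuffle_proportions Numeric vector of tip-shuffle proportions.
#' @param seeds Integer vector of replicate seeds.
#' @param methods Subset of `c("rpca", "phylo_rpca")`.
#' @param config Base [sim_config()]; depth/shuffle/seed are overridden per
#'   grid cell.
#' @param rank Ordination rank.
#' @param permutations PERMANOVA permutations (0 = F only, `p = NA`).
#' @param knn Evaluate KNN classification as well (set `FALSE` to skip).
#' @param tree_type Passed to the simulator (`"sorted"` or `"random"`).
#' @param k,folds,split KNN controls, see [knn_cv()].
#' @return Tibble with one row per (cell, method): `method`, `depth`,
#'   `shuffle_proportion`, `seed`, `F_statistic`, `permanova_p`, `pr_auc`,
#'   `roc_auc`.
#' @export
benchmark <- function(depths, shuffle_proportions = 0, seeds = 1:10,
                      methods = c("rpca", "phylo_rpca"),
                      config = sim_config(), rank = 3, permutations = 999,
                      knn = TRUE, tree_type = config$tree_type,
                      k = 3, folds = 10, split = 0.5) {
  methods <- match.arg(methods, c("rpca", "phylo_rpca"), several.ok = TRUE)
  grid <- expand.grid(depth = depths, shuffle = shuffle_proportions,
                      seed = seeds, stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid) * length(methods))
  ri <- 0
  for (gi in seq_len(nrow(grid))) {
    cfg <- config
    cfg$depth <- grid$depth[gi]
    cfg$shuffle_proportion <- grid$shuffle[gi]
    cfg$seed <- as.integer(grid$seed[gi])
    cfg$tree_type <- tree_type
    sim <- simulate_blocks(cfg)
    labels <- stats::setNames(sim$sample_labels$block, sim$sample_labels$sample)
    for (m in methods) {
      fit <- rpca(sim$counts,
                  tree = if (m == "phylo_rpca") sim$tree else NULL,
                  rank = rank, seed = cfg$seed)
      pv <- permanova(fit$distance, labels, permutations = permutations,
                      seed = derive_seed(cfg$seed, 11))
      if (knn) {
        kc <- knn_cv(fit$ordination$sample_scores, labels, k = k,
                     folds = folds, split = split,
                     seed = derive_seed(cfg$seed, 12))
      } else {
        kc <- tibble::tibble(pr_auc = NA_real_, roc_auc = NA_real_)
      }
      ri <- ri + 1
      rows[[ri]] <- tibble::tibble(
        method = m, depth = grid$depth[gi],
        shuffle_proportion = grid$shuffle[gi], seed = grid$seed[gi],
        F_statistic = pv$F_statistic, permanova_p = pv$p_value,
        pr_auc = kc$pr_auc, roc_auc = kc$roc_auc)
    }
  }
  if (ri == 0) {
    return(tibble::tibble(method = character(), depth = numeric(),
                          shuffle_proportion = numeric(), seed = integer(),
                          F_statistic = numeric(), permanova_p = numeric(),
                          pr_auc = numeric(), roc_auc = numeric()))
  }
  do.call(rbind, rows[seq_len(ri)])
}
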