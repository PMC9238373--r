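euclid_dist <- function(x) {
  d <- as.matrix(stats::dist(x))
  dimnames(d) <- list(names(x), names(x))
  d
}

test_that("permanova equals the classical ANOVA F on 1-D Euclidean data", {
  x <- stats::setNames(c(0, 1, 10, 11), letters[1:4])
  g <- stats::setNames(c("A", "A", "B", "B"), letters[1:4])
  res <- permanova(euclid_dist(x), g, permutations = 99, seed = 1)
  expect_equal(res$F_statistic, 200) # SS_between 100, SS_within 1, df 1/2
  # random 1-D data: agreement with aov
  for (seed in 1:3) {
    withr::with_seed(seed, {
      y <- rnorm(15)
      grp <- factor(rep(c("a", "b", "c"), each = 5))
    })
    names(y) <- paste0("s", 1:15)
    f_aov <- summary(stats::aov(y ~ grp))[[1]]$`F value`[1]
    f_perm <- permanova(euclid_dist(y),
                        stats::setNames(as.character(grp), names(y)),
                        permutations = 0)$F_statistic
    expect_equal(f_perm, f_aov, tolerance = 1e-10)
  }
})

test_that("permanova matches vegan::adonis2 and is invariant to ordering/relabeling", {
  withr::with_seed(42, {
    x <- matrix(rnorm(36), 12, 3)
    g <- sample(rep(c("u", "v", "w"), each = 4))
  })
  rownames(x) <- paste0("s", 1:12)
  names(g) <- rownames(x)
  D <- as.matrix(stats::dist(x))
  res <- permanova(D, g, permutations = 999, seed = 3)
  va <- vegan::adonis2(stats::dist(x) ~ grp, data = data.frame(grp = g),
                       permutations = 99)
  expect_equal(res$F_statistic, va$F[1], tolerance = 1e-10)
  # reorder samples
  perm <- sample(12)
  res2 <- permanova(D[perm, perm], g[perm], permutations = 0)
  expect_equal(res2$F_statistic, res$F_statistic, tolerance = 1e-12)
  # monotone relabeling of groups
  g2 <- stats::setNames(c(u = "1", v = "2", w = "3")[g], names(g))
  expect_equal(permanova(D, g2, permutations = 0)$F_statistic,
               res$F_statistic, tolerance = 1e-12)
})

test_that("permanova p-values are valid and inputs validated", {
  withr::with_seed(9, x <- stats::setNames(rnorm(12), paste0("s", 1:12)))
  g <- stats::setNames(rep(c("A", "B"), 6), names(x))
  res <- permanova(euclid_dist(x), g, permutations = 199, seed = 5)
  expect_gte(res$p_value, 1 / 200)
  expect_lte(res$p_value, 1)
  expect_error(permanova(euclid_dist(x), stats::setNames(rep("A", 12), names(x))),
               "2 groups")
  expect_error(permanova(euclid_dist(x), g[-1]), "unlabeled")
})

test_that("permanova holds its type-I error rate under the null", {
  n <- 20
  g <- stats::setNames(rep(c("A", "B"), each = n / 2), paste0("s", 1:n))
  reject <- 0
  trials <- 400
  for (i in seq_len(trials)) {
    withr::with_seed(1000 + i, x <- stats::setNames(rnorm(n), names(g)))
    p <- permanova(euclid_dist(x), g, permutations = 99,
                   seed = 2000 + i)$p_value
    reject <- reject + (p <= 0.05)
  }
  expect_gt(reject / trials, 0.02)
  expect_lt(reject / trials, 0.08)
})

test_that("average precision and ROC-AUC match brute-force/pROC oracles", {
  withr::with_seed(8, {
    for (i in 1:5) {
      score <- round(runif(30), 2) # ties likely
      truth <- rbinom(30, 1, 0.4)
      if (sum(truth) %in% c(0, 30)) next
      # brute-force AP: precision at every distinct threshold
      thr <- sort(unique(score), decreasing = TRUE)
      rec_prev <- 0
      ap <- 0
      for (t in thr) {
        sel <- score >= t
        prec <- sum(truth[sel]) / sum(sel)
        rec <- sum(truth[sel]) / sum(truth)
        ap <- ap + (rec - rec_prev) * prec
        rec_prev <- rec
      }
      expect_equal(average_precision(truth, score), ap, tolerance = 1e-12)
      expect_equal(rank_auc(truth, score),
                   as.numeric(pROC::auc(pROC::roc(truth, score, quiet = TRUE,
                                                  direction = "<"))),
                   tolerance = 1e-12)
    }
  })
})

test_that("knn_cv scores separated clusters perfectly and memorizes duplicates", {
  withr::with_seed(12, {
    sc <- rbind(matrix(rnorm(30, 0, 0.2), 15, 2),
                matrix(rnorm(30, 8, 0.2), 15, 2))
  })
  rownames(sc) <- paste0("s", 1:30)
  lab <- stats::setNames(rep(c("x", "y"), each = 15), rownames(sc))
  res <- knn_cv(sc, lab, k = 3, folds = 5, seed = 4)
  expect_equal(res$pr_auc, 1)
  expect_equal(res$roc_auc, 1)
  # duplicating every sample makes 50:50 splits memorizable
  sc2 <- rbind(sc, sc)
  rownames(sc2) <- paste0("d", 1:60)
  lab2 <- stats::setNames(rep(lab, 2), rownames(sc2))
  res2 <- knn_cv(sc2, lab2, k = 1, folds = 5, split = 0.5, seed = 4)
  expect_gt(res2$pr_auc, 0.95)
  expect_error(knn_cv(sc, stats::setNames(rep("x", 30), rownames(sc))),
               "2 classes")
})

test_that("knn_cv is at chance for labels independent of the scores", {
  aucs <- vapply(1:50, function(seed) {
    withr::with_seed(seed, {
      sc <- matrix(rnorm(80), 40, 2)
      lab <- rep(c("a", "b"), each = 20)
    })
    rownames(sc) <- paste0("s", 1:40)
    res <- knn_cv(sc, stats::setNames(lab, rownames(sc)), k = 3, folds = 3,
                  seed = seed + 100)
    c(res$pr_auc, res$roc_auc)
  }, c(0, 0))
  expect_equal(mean(aucs[1, ]), 0.5, tolerance = 0.1)
  expect_equal(mean(aucs[2, ]), 0.5, tolerance = 0.1)
})

test_that("benchmark assembles one row per grid cell and method", {
  cfg <- tiny_config()
  res <- benchmark(depths = 2000, shuffle_proportions = 0, seeds = 1:2,
                   config = cfg, permutations = 49, folds = 3, k = 2)
  expect_equal(nrow(res), 4) # 2 methods x 2 seeds
  expect_setequal(unique(res$method), c("rpca", "phylo_rpca"))
  expect_true(all(res$F_statistic >= 0))
  expect_true(all(res$pr_auc >= 0 & res$pr_auc <= 1))
  empty <- benchmark(depths = numeric(0), seeds = integer(0), config = cfg)
  expect_equal(nrow(empty), 0)
  res2 <- benchmark(depths = 2000, shuffle_proportions = 0, seeds = 1:2,
                    config = cfg, permutations = 49, folds = 3, k = 2)
  expect_equal(res, res2)
})
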