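test_that("masked_factorize recovers exact low-rank structure and completes entries", {
  # dense rank-1
  X <- matrix(c(1, 2, 2, 4), 2)
  f <- masked_factorize(X, rank = 1, seed = 1, tol = 1e-14)
  expect_lt(max(abs(f$u %*% diag(f$d, 1) %*% t(f$v) - X)), 1e-8)
  # rank-1 completion: missing entry determined by the rank-1 closure
  Xm <- matrix(c(1, 2, 2, NA), 2)
  f2 <- masked_factorize(Xm, rank = 1, seed = 1, tol = 1e-14)
  expect_equal((f2$u %*% diag(f2$d, 1) %*% t(f2$v))[2, 2], 4, tolerance = 1e-6)
  expect_error(masked_factorize(matrix(rnorm(12), 3, 4), rank = 5), "rank")
})

test_that("masked_factorize agrees with truncated SVD on dense input", {
  withr::with_seed(21, {
    # planted spectrum with clear gaps so the subspace is well conditioned
    U <- qr.Q(qr(matrix(rnorm(10 * 3), 10, 3)))
    V <- qr.Q(qr(matrix(rnorm(8 * 3), 8, 3)))
    X <- U %*% diag(c(9, 5, 2)) %*% t(V) + matrix(rnorm(80, 0, 0.01), 10, 8)
  })
  f <- masked_factorize(X, rank = 3, seed = 2, tol = 1e-13, max_iter = 5000)
  sv <- svd(X)
  expect_equal(f$d, sv$d[1:3], tolerance = 1e-8)
  rec_als <- f$u %*% diag(f$d) %*% t(f$v)
  rec_svd <- sv$u[, 1:3] %*% diag(sv$d[1:3]) %*% t(sv$v[, 1:3])
  expect_lt(max(abs(rec_als - rec_svd)), 1e-6)
})

test_that("objective is monotone nonincreasing and runs are seed-deterministic", {
  m <- rclr(sparse_counts(9, 14, seed = 2))
  dc <- double_center(m)
  f <- masked_factorize(dc, rank = 3, seed = 5)
  expect_true(all(diff(f$objective) <= 1e-8 * (1 + f$objective[-length(f$objective)])))
  f2 <- masked_factorize(dc, rank = 3, seed = 5)
  expect_identical(f$u, f2$u)
  expect_identical(f$d, f2$d)
  expect_identical(f$v, f2$v)
})

test_that("planted rank-2 structure is recovered through 20% masking", {
  withr::with_seed(31, {
    U <- matrix(rnorm(20 * 2), 20, 2)
    V <- matrix(rnorm(15 * 2), 15, 2)
    X <- U %*% t(V)
    mask <- matrix(runif(300) > 0.2, 20, 15)
  })
  Xm <- ifelse(mask, X, NA)
  f <- masked_factorize(Xm, rank = 2, seed = 3, tol = 1e-13, max_iter = 5000)
  rec <- f$u %*% diag(f$d) %*% t(f$v)
  expect_lt(sqrt(sum((rec - X)^2)) / sqrt(sum(X^2)), 0.05)
})

test_that("rpca ordination and distances behave on duplicates, order, and trees", {
  tab <- sparse_counts(8, 12, seed = 17)
  tab <- rbind(tab, dup = tab["s3", ]) # duplicated sample
  rownames(tab)[nrow(tab)] <- "dup"
  fit <- rpca(tab, rank = 2, seed = 1, tol = 1e-12)
  expect_lt(fit$distance["s3", "dup"], 1e-6)
  # metric axioms
  D <- fit$distance
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-8)
  # sample permutation permutes output identically
  perm <- c(4, 1, 3, 2, 5, 9, 7, 8, 6)
  fitp <- rpca(tab[perm, ], rank = 2, seed = 1, tol = 1e-12)
  expect_equal(fitp$distance, fit$distance[perm, perm], tolerance = 1e-9)
  # star unit tree == no tree
  star <- parse_newick(paste0("(", paste0(colnames(tab), ":1", collapse = ","), ");"))
  fits <- rpca(tab, tree = star, rank = 2, seed = 1, tol = 1e-12)
  expect_lt(max(abs(fits$distance - fit$distance)), 1e-8)
  # proportion explained well-formed
  pe <- fit$ordination$proportion_explained
  expect_true(all(pe >= 0 & pe <= 1))
  expect_lte(sum(pe), 1)
  expect_true(all(diff(fit$ordination$eigenvalues) <= 1e-10))
})

test_that("rpca clamps an oversized rank with a warning", {
  tab <- sparse_counts(4, 10, seed = 23)
  expect_warning(fit <- rpca(tab, rank = 5, seed = 1), "clamped")
  expect_equal(fit$ordination$rank, 3)
})

test_that("rank_loadings orders signed loadings and validates the axis", {
  ord <- new_ordination(
    d = 2, prop = 0.5,
    scores = matrix(0, 2, 1, dimnames = list(c("s1", "s2"), "PC1")),
    loadings = matrix(c(2, 0, -2), 3, 1, dimnames = list(c("A", "B", "C"), "PC1")))
  rl <- rank_loadings(ord, axis = 1, top_k = 1)
  expect_equal(rl$node_id[rl$direction == "positive"], "A")
  expect_equal(rl$node_id[rl$direction == "negative"], "C")
  expect_warning(rank_loadings(ord, axis = 1, top_k = 10), "clamped")
  expect_error(rank_loadings(ord, axis = 0), "axis")
  expect_error(rank_loadings(ord, axis = 2), "axis")
})
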