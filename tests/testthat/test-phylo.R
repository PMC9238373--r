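test_that("parse_newick reads topology, assigns postorder internal IDs, round-trips", {
  tr <- toy_tree()
  expect_s3_class(tr, "phylo")
  expect_equal(ape::Ntip(tr), 3)
  expect_equal(tr$Nnode, 2)
  expect_equal(postorder_nodes(tr), c("A", "B", "n1", "C", "root"))
  # unnamed internal nodes get n<postorder rank>
  tr2 <- parse_newick("((A:1,B:2):0.5,C:3);")
  expect_equal(sort(tr2$node.label), c("n1", "n2"))
  expect_equal(postorder_nodes(tr2), c("A", "B", "n1", "C", "n2"))
  rt <- parse_newick(write_newick(tr))
  expect_equal(postorder_nodes(rt), postorder_nodes(tr))
  expect_equal(tip_depths(rt), tip_depths(tr))
})

test_that("parse_newick rejects malformed input and defaults missing lengths", {
  expect_error(parse_newick(""), "empty newick")
  expect_error(parse_newick("((A:1,B:2,C:1);"), "unbalanced")
  expect_error(parse_newick("((A:1,A:2):1,C:1);"), "duplicate tip name A")
  expect_warning(tr <- parse_newick("((A,B),C);"), "defaulting to 1")
  expect_true(all(tr$edge.length == 1))
})

test_that("expand_table aggregates descendant tips with branch weights", {
  ex <- expand_table(toy_counts()[1, , drop = FALSE], toy_tree())
  expect_equal(colnames(ex$counts), c("A", "B", "n1", "C"))
  expect_equal(ex$counts["s1", ], c(A = 1, B = 2, n1 = 3, C = 3))
  expect_equal(ex$weights, c(A = 1, B = 2, n1 = 0.5, C = 3))
  # all-zero sample stays all-zero
  z <- toy_counts()
  z["s2", ] <- 0
  expect_true(all(expand_table(z, toy_tree())$counts["s2", ] == 0))
  # unknown feature errors
  bad <- toy_counts()
  colnames(bad) <- c("A", "B", "D")
  expect_error(expand_table(bad, toy_tree()), "absent from tree")
  expect_error(expand_table(-toy_counts(), toy_tree()), "negative")
})

test_that("expansion conservation: node columns equal brute-force tip sums, root sum is sample total", {
  for (seed in 1:4) {
    tips <- paste0("t", 1:12)
    tr <- rand_tree(tips, seed = seed)
    tab <- sparse_counts(6, 12, seed = seed)
    colnames(tab) <- tips
    ex <- expand_table(tab, tr)
    for (nd in colnames(ex$counts)) {
      under <- tips_under(ex$tree, nd)
      expect_equal(ex$counts[, nd], rowSums(tab[, under, drop = FALSE]),
                   ignore_attr = TRUE)
    }
    # children of the root sum to the sample totals
    root_kids <- ex$tree$edge[ex$tree$edge[, 1] == ape::Ntip(ex$tree) + 1L, 2]
    kid_names <- node_names(ex$tree)[root_kids]
    expect_equal(unname(rowSums(ex$counts[, kid_names, drop = FALSE])),
                 unname(rowSums(tab)))
  }
})

test_that("expand_table drops zero-weight nodes", {
  tr <- parse_newick("((A:1,B:1)n1:0,C:1);")
  ex <- expand_table(toy_counts()[1, , drop = FALSE], tr)
  expect_false("n1" %in% colnames(ex$counts))
  expect_true(all(ex$weights > 0))
})

test_that("prune_tree shears, collapses chains, and preserves path lengths", {
  pr <- prune_tree(toy_tree(), c("A", "C"))
  expect_setequal(pr$tip.label, c("A", "C"))
  expect_equal(unname(tip_depths(pr)["A"]), 1.5) # 1 + 0.5 through collapsed n1
  # identity when keeping everything
  all_pr <- prune_tree(toy_tree(), c("A", "B", "C"))
  expect_equal(tip_depths(all_pr), tip_depths(toy_tree()))
  expect_error(prune_tree(toy_tree(), character(0)), "empty")
  expect_error(prune_tree(toy_tree(), c("A", "Z")), "not in tree")
  # property: retained tip depths unchanged on random trees
  for (seed in 5:7) {
    tr <- rand_tree(paste0("t", 1:10), seed = seed)
    keep <- paste0("t", c(1, 3, 5, 8))
    pr <- prune_tree(tr, keep)
    expect_equal(tip_depths(pr)[keep], tip_depths(tr)[keep], tolerance = 1e-9)
  }
})

test_that("prune_tree min_subtree_tips contracts small clades without touching tips", {
  tr <- parse_newick("(((A:1,B:1)n1:1,(C:1,D:1)n2:1)n3:1,(E:1,F:1)n4:1);")
  pr <- prune_tree(tr, c("A", "B", "C", "E", "F"), min_subtree_tips = 2)
  expect_setequal(pr$tip.label, c("A", "B", "C", "E", "F"))
  # C became a single-tip subtree under n2 -> n2 collapsed by shear;
  # larger clades survive
  expect_equal(tip_depths(pr)[c("A", "C", "E")],
               tip_depths(tr)[c("A", "C", "E")], tolerance = 1e-9)
  pr3 <- prune_tree(tr, tr$tip.label, min_subtree_tips = 3)
  expect_equal(tip_depths(pr3), tip_depths(tr), tolerance = 1e-9)
  # only nodes with >= 3 descendant tips survive (plus the root)
  sizes <- subtree_tip_counts(pr3)
  internal <- (ape::Ntip(pr3) + 2):(ape::Ntip(pr3) + pr3$Nnode)
  if (length(internal) && pr3$Nnode > 1)
    expect_true(all(sizes[internal] >= 3))
})

test_that("shuffle_tips permutes the chosen subset reproducibly", {
  tr <- rand_tree(paste0("t", 1:20), seed = 2)
  expect_equal(shuffle_tips(tr, 0, seed = 1), tr)
  s1 <- shuffle_tips(tr, 1, seed = 9)
  expect_setequal(s1$tip.label, tr$tip.label)
  expect_equal(s1$edge, tr$edge)
  expect_equal(s1$edge.length, tr$edge.length)
  expect_equal(shuffle_tips(tr, 1, seed = 9)$tip.label, s1$tip.label)
  # proportion 0.5 of 4 tips: exactly 2 labels eligible to move
  tr4 <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  moved <- vapply(1:50, function(s)
    sum(shuffle_tips(tr4, 0.5, seed = s)$tip.label != tr4$tip.label), 0)
  expect_true(all(moved %in% c(0, 2))) # a 2-subset either swaps or stays
  expect_error(shuffle_tips(tr, 1.2, seed = 1), "proportion")
})

test_that("random_tree is binary, seeded, and covers the requested tips", {
  tips <- paste0("x", 1:9)
  tr <- random_tree(tips, seed = 4)
  expect_setequal(tr$tip.label, tips)
  expect_equal(tr$Nnode, length(tips) - 1) # binary rooted
  expect_identical(write_newick(random_tree(tips, seed = 4)), write_newick(tr))
  expect_false(identical(write_newick(random_tree(tips, seed = 5)),
                         write_newick(tr)))
  one <- random_tree("solo", seed = 1)
  expect_equal(one$tip.label, "solo")
  expect_equal(one$Nnode, 1) # just the root
  expect_error(random_tree(c("a", "a"), seed = 1), "duplicate")
  expect_error(random_tree(character(0), seed = 1), "empty")
})

test_that("tips_under returns descendant tip sets", {
  tr <- toy_tree()
  expect_setequal(tips_under(tr, "n1"), c("A", "B"))
  expect_equal(tips_under(tr, "A"), "A")
  expect_setequal(tips_under(tr, "root"), c("A", "B", "C"))
  expect_error(tips_under(tr, "nX"), "unknown node")
})
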