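#' Parse a rooted newick string into an indexed phylogeny
#'
#' Reads a newick tree (string or file), validates it, and assigns stable IDs
#' to unnamed internal nodes in the form `n<k>`, where `k` is the node's rank
#' among internal nodes in postorder. Named internal nodes keep their names.
#' Branch lengths are required downstream as node weights; when a tree carries
#' none they default to 1 with a warning.
#'
#' @param text A newick string (must end in `;`).
#' @param file Alternatively, path to a newick file.
#' @return An `ape::phylo` tree, rooted, with unique `tip.label` and a full
#'   `node.label` vector.
#' @examples
#' tr <- parse_newick("((A:1,B:2)n1:0.5,C:3)root;")
#' postorder_nodes(tr)
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("supply `text` or `file`", call. = FALSE)
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  text <- trimws(text)
  if (!nzchar(text)) stop("empty newick", call. = FALSE)
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) stop("unbalanced parentheses in newick", call. = FALSE)
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("malformed newick: ", conditionMessage(e), call. = FALSE))
  if (is.null(tree)) stop("malformed newick", call. = FALSE)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop("duplicate tip name ", paste(dup, collapse = ", "), call. = FALSE)
  if (is.null(tree$edge.length)) {
    warning("newick has no branch lengths; defaulting to 1.0")
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    warning("missing branch lengths; defaulting to 1.0")
    tree$edge.length[is.na(tree$edge.length)] <- 1
  }
  if (any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed", call. = FALSE)
  label_internal_nodes(tree)
}

#' Write a phylogeny as newick
#'
#' @param tree An `ape::phylo` tree.
#' @param file Output path; when `NULL` the newick string is returned.
#' @return The newick string, invisibly when written to file.
#' @export
write_newick <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

# fill empty internal node labels with n<postorder rank among internal nodes>
label_internal_nodes <- function(tree) {
  ntip <- ape::Ntip(tree)
  lab <- tree$node.label %||% rep("", tree$Nnode)
  lab[is.na(lab)] <- ""
  po <- postorder_index(tree)
  int_po <- po[po > ntip]
  taken <- c(tree$tip.label, lab[nzchar(lab)])
  for (k in seq_along(int_po)) {
    j <- int_po[k] - ntip
    if (!nzchar(lab[j])) {
      cand <- paste0("n", k)
      while (cand %in% taken) cand <- paste0(cand, "_")
      lab[j] <- cand
      taken <- c(taken, cand)
    }
  }
  if (anyDuplicated(lab))
    stop("duplicate internal node labels", call. = FALSE)
  tree$node.label <- lab
  tree
}

# left-to-right postorder sequence of ape node indices (every child before
# its parent, root last, children visited in cladewise/newick order)
postorder_index <- function(tree) {
  ntip <- ape::Ntip(tree)
  n <- ntip + tree$Nnode
  kids <- split(tree$edge[, 2], factor(tree$edge[, 1], levels = seq_len(n)))
  out <- integer(n)
  pos <- 0L
  rec <- function(v) {
    for (ch in kids[[v]]) rec(ch)
    pos <<- pos + 1L
    out[pos] <<- v
  }
  rec(ntip + 1L)
  out
}

node_names <- function(tree) {
  stopifnot(!is.null(tree$node.label))
  c(tree$tip.label, tree$node.label)
}

#' Postorder node names of a phylogeny
#'
#' @param tree An `ape::phylo` tree with node labels (see [parse_newick()]).
#' @return Character vector of all node names in postorder (children before
#'   parents, root last).
#' @export
postorder_nodes <- function(tree) {
  node_names(tree)[postorder_index(tree)]
}

#' Expand a count table to all nodes of a phylogeny
#'
#' Builds the Fast UniFrac count array: one column per non-root tree node, in
#' postorder, where each internal node's column is the per-sample sum of the
#' counts of its descendant tips. Each node carries a weight equal to the
#' length of the branch above it; zero-weight nodes are dropped from both the
#' table and the weight vector, and the root (which has no branch) is never
#' included.
#'
#' @param table Samples x features count matrix; every feature must be a tip.
#' @param tree A rooted `ape::phylo`; tips not present in `table` are sheared
#'   off first.
#' @return A list with `counts` (samples x nodes matrix, postorder columns),
#'   `weights` (named branch-length vector aligned to the columns) and `tree`
#'   (the sheared, labeled tree actually used).
#' @examples
#' tr <- parse_newick("((A:1,B:2)n1:0.5,C:3)root;")
#' tab <- matrix(c(1, 2, 3), 1, dimnames = list("s1", c("A", "B", "C")))
#' expand_table(tab, tr)$counts
#' @export
expand_table <- function(table, tree) {
  check_count_table(table)
  feats <- colnames(table)
  missing <- setdiff(feats, tree$tip.label)
  if (length(missing))
    stop("features absent from tree: ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  if (length(setdiff(tree$tip.label, feats)))
    tree <- prune_tree(tree, feats)
  tree <- label_internal_nodes(tree)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  X <- matrix(0, nrow(table), nn)
  X[, seq_len(ntip)] <- table[, tree$tip.label, drop = FALSE]
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge)))
    X[, po$edge[e, 1]] <- X[, po$edge[e, 1]] + X[, po$edge[e, 2]]
  # column order: left-to-right postorder, root excluded
  ord <- postorder_index(tree)
  ord <- ord[ord != ntip + 1L]
  elen_by_node <- numeric(nn)
  elen_by_node[tree$edge[, 2]] <- tree$edge.length
  counts <- X[, ord, drop = FALSE]
  dimnames(counts) <- list(rownames(table), node_names(tree)[ord])
  weights <- stats::setNames(elen_by_node[ord], node_names(tree)[ord])
  keep <- weights > 0
  if (!all(keep)) {
    counts <- counts[, keep, drop = FALSE]
    weights <- weights[keep]
  }
  list(counts = counts, weights = weights, tree = tree)
}

#' Shear a phylogeny to a set of tips
#'
#' Keeps exactly `keep_tips`, collapsing unary internal chains with branch
#' lengths summed so that tip-to-root path lengths are preserved. Optionally,
#' internal nodes whose subtree retains fewer than `min_subtree_tips` tips are
#' contracted (their children reattach to the grandparent, branch lengths
#' added), removing them from downstream node expansion while leaving the tip
#' set and path lengths intact.
#'
#' @param tree An `ape::phylo` tree.
#' @param keep_tips Character vector of tip names to retain (subset of tips).
#' @param min_subtree_tips Minimum number of retained descendant tips an
#'   internal node needs to survive; 1 (default) disables contraction.
#' @return The sheared tree with internal labels reassigned where needed.
#' @export
prune_tree <- function(tree, keep_tips, min_subtree_tips = 1) {
  keep_tips <- unique(as.character(keep_tips))
  if (!length(keep_tips)) stop("keep_tips is empty", call. = FALSE)
  extra <- setdiff(keep_tips, tree$tip.label)
  if (length(extra))
    stop("keep_tips not in tree: ", paste(utils::head(extra, 5), collapse = ", "),
         call. = FALSE)
  tree <- label_internal_nodes(tree)
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  n <- ntip + tree$Nnode
  kids <- split(tree$edge[, 2], factor(tree$edge[, 1], levels = seq_len(n)))
  elen <- numeric(n)
  elen[tree$edge[, 2]] <- tree$edge.length
  labs <- node_names(tree)
  keep <- tree$tip.label %in% keep_tips
  fmt <- function(it) sprintf("%s:%.12g", it$str, it$len)
  # returns a list of subtree items (newick string + pending branch length);
  # unary chains and small internal nodes dissolve into their parent with
  # branch lengths added, so retained tip-to-root path lengths never change
  rec <- function(v) {
    if (v <= ntip) {
      if (!keep[v]) return(list())
      return(list(list(str = labs[v], len = elen[v], tips = 1L)))
    }
    items <- unlist(lapply(kids[[v]], rec), recursive = FALSE)
    if (!length(items) || v == root) return(items)
    add <- function(it) { it$len <- it$len + elen[v]; it }
    if (length(items) == 1) return(list(add(items[[1]])))
    ntips <- sum(vapply(items, `[[`, 0L, "tips"))
    if (ntips < min_subtree_tips) return(lapply(items, add))
    inner <- paste(vapply(items, fmt, ""), collapse = ",")
    list(list(str = sprintf("(%s)%s", inner, labs[v]), len = elen[v],
              tips = ntips))
  }
  items <- rec(root)
  txt <- sprintf("(%s)%s;", paste(vapply(items, fmt, ""), collapse = ","),
                 labs[root])
  label_internal_nodes(ape::read.tree(text = txt))
}

# number of descendant tips of every node (tips count as 1), indexed by
# ape node index
subtree_tip_counts <- function(tree) {
  ntip <- ape::Ntip(tree)
  n <- ntip + tree$Nnode
  cnt <- c(rep(1L, ntip), rep(0L, tree$Nnode))
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(edge)))
    cnt[edge[e, 1]] <- cnt[edge[e, 1]] + cnt[edge[e, 2]]
  cnt
}

# root-to-tip path lengths, named by tip
tip_depths <- function(tree) {
  ntip <- ape::Ntip(tree)
  n <- ntip + tree$Nnode
  depth <- numeric(n)
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  elen <- ape::reorder.phylo(tree, "postorder")$edge.length
  for (e in rev(seq_len(nrow(edge))))
    depth[edge[e, 2]] <- depth[edge[e, 1]] + elen[e]
  stats::setNames(depth[seq_len(ntip)], tree$tip.label)
}

#' Randomly shuffle a proportion of tip labels
#'
#' Topology and branch lengths are untouched; `round(proportion * n_tips)`
#' tips are chosen uniformly and their labels permuted uniformly among
#' themselves (fixed points allowed). Used to desynchronize a phylogeny from
#' the sample structure in benchmarks.
#'
#' @param tree An `ape::phylo` tree.
#' @param proportion Fraction of tips to shuffle, in `[0, 1]`.
#' @param seed Integer RNG seed; the same seed reproduces the same shuffle.
#' @return The relabeled tree.
#' @export
shuffle_tips <- function(tree, proportion, seed = 1) {
  if (!is.numeric(proportion) || length(proportion) != 1 ||
      is.na(proportion) || proportion < 0 || proportion > 1)
    stop("proportion must be in [0, 1]", call. = FALSE)
  ntip <- ape::Ntip(tree)
  k <- round(proportion * ntip)
  if (k < 2) return(tree)
  withr::with_seed(as.integer(seed), {
    sel <- sample.int(ntip, k)
    tree$tip.label[sel] <- tree$tip.label[sel][sample.int(k)]
  })
  tree
}

#' Generate a seeded random phylogeny over given tips
#'
#' Draws a random binary rooted topology over `tip_ids` with exponential
#' (mean 1) branch lengths. The result deliberately carries no phylogenetic
#' signal with respect to any structure among the tips, serving as the null
#' tree in benchmarks.
#'
#' @param tip_ids Character vector of unique tip names.
#' @param seed Integer RNG seed.
#' @return An `ape::phylo` tree with `length(tip_ids)` tips.
#' @export
random_tree <- function(tip_ids, seed = 1) {
  tip_ids <- as.character(tip_ids)
  if (!length(tip_ids)) stop("tip_ids is empty", call. = FALSE)
  if (anyDuplicated(tip_ids)) stop("duplicate tip_ids", call. = FALSE)
  n <- length(tip_ids)
  tree <- withr::with_seed(as.integer(seed), {
    if (n == 1) {
      ape::read.tree(text = sprintf("(%s:%.12g);", tip_ids, stats::rexp(1)))
    } else {
      ape::rtree(n, tip.label = tip_ids, br = function(k) stats::rexp(k))
    }
  })
  label_internal_nodes(tree)
}

#' Tips descending from a node
#'
#' @param tree An `ape::phylo` tree with node labels.
#' @param node_id A tip or internal node name.
#' @return Character vector of descendant tip names (the node itself when it
#'   is a tip).
#' @export
tips_under <- function(tree, node_id) {
  tree <- label_internal_nodes(tree)
  labs <- node_names(tree)
  idx <- match(node_id, labs)
  if (is.na(idx)) stop("unknown node: ", node_id, call. = FALSE)
  ntip <- ape::Ntip(tree)
  if (idx <= ntip) return(tree$tip.label[idx])
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  out <- character(0)
  stack <- idx
  while (length(stack)) {
    v <- stack[[1]]
    stack <- stack[-1]
    if (v <= ntip) out <- c(out, tree$tip.label[v])
    else stack <- c(kids[[as.character(v)]], stack)
  }
  out
}
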