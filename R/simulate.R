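#' Configuration for the three-block microbiome simulation
#'
#' The simulator emulates a community in which most features are most
#' abundant in exactly one of a few sample groups (environment blocks), with
#' a minority shared between groups. Feature and sample positions live on a
#' latent 1-D environmental axis: feature optima `mu_i` scatter around their
#' block's center, sample positions `g_j` scatter more tightly around the
#' same centers, and the pre-noise intensity of feature `i` in sample `j` is
#' the Gaussian kernel `exp(-(mu_i - g_j)^2 / (2 sigma^2)) / sqrt(2 pi sigma^2)`.
#' Intensities receive additive Gaussian plus uniform noise, are clipped at
#' zero, and closed per sample; counts are then drawn Poisson-lognormally at
#' a set sequencing depth.
#'
#' @param n_blocks Number of sample groups / feature blocks (default 3).
#' @param features_per_block Features whose optimum lies in each block.
#' @param samples_per_block Samples per group.
#' @param sigma Kernel width of the abundance response (axis units).
#' @param block_centers Axis positions of the blocks (default 0, 5, 10, ...).
#' @param overlap_fraction Fraction of all features re-drawn uniformly across
#'   the axis span, shared between groups.
#' @param noise_sd Scale of the additive Gaussian and uniform intensity noise
#'   (the noiseless peak intensity is `1/sqrt(2 pi sigma^2)` ~ 0.4 at
#'   `sigma = 1`).
#' @param depth Sequencing depth (reads/sample).
#' @param phi Poisson-lognormal overdispersion (sd of the log intensity).
#' @param shuffle_proportion Fraction of tree tip labels to shuffle.
#' @param tree_type `"sorted"` (block-synchronized caterpillar) or
#'   `"random"` (null tree, no signal).
#' @param seed Integer master seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_blocks = 3, features_per_block = 100,
                       samples_per_block = 20, sigma = 1,
                       block_centers = seq(0, by = 5, length.out = n_blocks),
                       overlap_fraction = 0.1, noise_sd = 0.01,
                       depth = 2e6, phi = 0.5, shuffle_proportion = 0,
                       tree_type = c("sorted", "random"), seed = 1) {
  tree_type <- match.arg(tree_type)
  cfg <- list(n_blocks = as.integer(n_blocks),
              features_per_block = as.integer(features_per_block),
              samples_per_block = as.integer(samples_per_block),
              sigma = sigma, block_centers = block_centers,
              overlap_fraction = overlap_fraction, noise_sd = noise_sd,
              depth = depth, phi = phi,
              shuffle_proportion = shuffle_proportion,
              tree_type = tree_type, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_blocks >= 1, cfg$features_per_block >= 1,
            cfg$samples_per_block >= 1)
  if (cfg$sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (length(cfg$block_centers) != cfg$n_blocks)
    stop("block_centers must have one entry per block", call. = FALSE)
  if (cfg$depth < 0) stop("depth must be >= 0", call. = FALSE)
  if (cfg$phi < 0) stop("phi must be >= 0", call. = FALSE)
  if (cfg$shuffle_proportion < 0 || cfg$shuffle_proportion > 1)
    stop("shuffle_proportion must be in [0, 1]", call. = FALSE)
  if (cfg$overlap_fraction < 0 || cfg$overlap_fraction >= 1)
    stop("overlap_fraction must be in [0, 1)", call. = FALSE)
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  invisible(cfg)
}

#' Block-structured proportion matrix
#'
#' Draws the latent feature/sample positions, evaluates the Gaussian kernel
#' intensity, adds noise, clips at zero and closes each sample to proportions.
#'
#' @param cfg A [sim_config()].
#' @return List with `p` (samples x features row-closed proportions),
#'   `feature_block` (named block label per feature, `"shared"` for overlap
#'   features), `sample_block` (named label per sample) and
#'   `features_by_block` (list of feature IDs per block, in axis order).
#' @export
block_proportions <- function(cfg) {
  validate_sim_config(cfg)
  nb <- cfg$n_blocks
  nf <- nb * cfg$features_per_block
  ns <- nb * cfg$samples_per_block
  feats <- sprintf("f%04d", seq_len(nf))
  samps <- sprintf("s%03d", seq_len(ns))
  fblk <- rep(seq_len(nb), each = cfg$features_per_block)
  sblk <- rep(seq_len(nb), each = cfg$samples_per_block)
  withr::with_seed(derive_seed(cfg$seed, 1), {
    mu <- cfg$block_centers[fblk] + stats::rnorm(nf, 0, cfg$sigma)
    g <- cfg$block_centers[sblk] + stats::rnorm(ns, 0, cfg$sigma / 2)
    n_shared <- round(cfg$overlap_fraction * nf)
    shared <- if (n_shared > 0) sample.int(nf, n_shared) else integer(0)
    mu[shared] <- stats::runif(n_shared, min(cfg$block_centers), max(cfg$block_centers))
    x <- outer(g, mu, function(gj, mi)
      exp(-(mi - gj)^2 / (2 * cfg$sigma^2)) / sqrt(2 * pi * cfg$sigma^2))
    x <- x + matrix(stats::rnorm(ns * nf, 0, cfg$noise_sd), ns, nf) +
      matrix(stats::runif(ns * nf, -cfg$noise_sd, cfg$noise_sd), ns, nf)
  })
  x <- pmax(x, 0)
  if (any(rowSums(x) <= 0)) stop("degenerate config: empty sample", call. = FALSE)
  dimnames(x) <- list(samps, feats)
  labs <- as.character(fblk)
  labs[shared] <- "shared"
  fb <- lapply(seq_len(nb), function(b) feats[fblk == b])
  names(fb) <- paste0("block", seq_len(nb))
  list(p = closure(x),
       feature_block = stats::setNames(labs, feats),
       sample_block = stats::setNames(paste0("block", sblk), samps),
       features_by_block = fb)
}

#' Poisson-lognormal count sampling
#'
#' Given row-closed proportions `p`, draws counts
#' `y_ij ~ Poisson(n * p_ij * exp(e_ij))` with `e_ij ~ Normal(0, phi^2)`.
#' `phi = 0` is plain Poisson sampling at expected depth `n`; for `phi > 0`
#' the expected depth is inflated by `exp(phi^2 / 2)`.
#'
#' @param p Samples x features row-closed proportion matrix.
#' @param depth Expected reads per sample (`n`).
#' @param phi Lognormal overdispersion (sd of the log intensity).
#' @param seed Integer seed.
#' @return Integer count matrix of the same shape.
#' @export
pln_sample <- function(p, depth, phi = 0, seed = 1) {
  if (depth < 0) stop("depth must be >= 0", call. = FALSE)
  if (phi < 0) stop("phi must be >= 0", call. = FALSE)
  if (max(abs(rowSums(p) - 1)) > 1e-6) stop("p rows must sum to 1", call. = FALSE)
  lam <- depth * p
  y <- withr::with_seed(as.integer(seed), {
    if (phi > 0)
      lam <- lam * exp(matrix(stats::rnorm(length(lam), 0, phi), nrow(lam)))
    matrix(stats::rpois(length(lam), lam), nrow(lam))
  })
  dimnames(y) <- dimnames(p)
  storage.mode(y) <- "integer"
  y
}

#' Block-sorted caterpillar-of-clades phylogeny
#'
#' Builds a tree whose postorder tip sequence equals the concatenated block
#' order: each block becomes a balanced clade over its features in the given
#' order, and the clades are chained left-to-right (a caterpillar at the
#' block level). All branch lengths are 1. This is the fully
#' block-synchronized phylogeny: internal nodes aggregate contiguous runs of
#' same-block features at every scale.
#'
#' @param feature_ids_by_block List of disjoint, nonempty character vectors.
#' @return An `ape::phylo` tree.
#' @examples
#' tr <- sorted_block_tree(list(c("A", "B"), c("C", "D")))
#' postorder_nodes(tr)
#' @export
sorted_block_tree <- function(feature_ids_by_block) {
  if (!length(feature_ids_by_block)) stop("no blocks", call. = FALSE)
  if (any(lengths(feature_ids_by_block) == 0)) stop("empty block", call. = FALSE)
  all_ids <- unlist(feature_ids_by_block)
  if (anyDuplicated(all_ids))
    stop("overlapping feature IDs between blocks: ",
         all_ids[duplicated(all_ids)][1], call. = FALSE)
  addlen <- function(s) paste0(s, ":1")
  balanced <- function(tips) {
    if (length(tips) == 1) return(tips)
    h <- ceiling(length(tips) / 2)
    sprintf("(%s,%s)", addlen(balanced(tips[seq_len(h)])),
            addlen(balanced(tips[-seq_len(h)])))
  }
  clades <- vapply(feature_ids_by_block, balanced, "")
  s <- clades[1]
  for (cl in clades[-1]) s <- sprintf("(%s,%s)", addlen(s), addlen(cl))
  if (length(all_ids) == 1 || !startsWith(s, "(")) s <- sprintf("(%s)", addlen(s))
  parse_newick(paste0(s, ";"))
}

#' Run the full block simulation
#'
#' Chains [block_proportions()], [pln_sample()] and the tree construction:
#' a block-sorted phylogeny optionally desynchronized with [shuffle_tips()],
#' or a [random_tree()] null tree. All randomness derives from `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return List with `counts` (samples x features), `sample_labels` (tibble
#'   `sample`, `block`), `tree`, `truth` (list: `feature_block`, `p`) and
#'   `config`.
#' @export
simulate_blocks <- function(cfg = sim_config()) {
  validate_sim_config(cfg)
  bp <- block_proportions(cfg)
  counts <- pln_sample(bp$p, cfg$depth, cfg$phi, seed = derive_seed(cfg$seed, 2))
  tree <- if (cfg$tree_type == "random") {
    random_tree(colnames(bp$p), seed = derive_seed(cfg$seed, 3))
  } else {
    shuffle_tips(sorted_block_tree(bp$features_by_block),
                 cfg$shuffle_proportion, seed = derive_seed(cfg$seed, 4))
  }
  list(counts = counts,
       sample_labels = tibble::tibble(sample = rownames(counts),
                                      block = unname(bp$sample_block)),
       tree = tree,
       truth = list(feature_block = bp$feature_block, p = bp$p),
       config = cfg)
}
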