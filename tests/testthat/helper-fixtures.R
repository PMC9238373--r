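# fixtures built in code; everything deterministic under fixed seeds

toy_tree <- function() parse_newick("((A:1,B:2)n1:0.5,C:3)root;")

toy_counts <- function() {
  matrix(c(1, 2, 3,
           4, 0, 6),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("s1", "s2"), c("A", "B", "C")))
}

# dense positive counts (no zeros) for exact-equivalence checks
dense_counts <- function(n = 8, p = 12, seed = 42) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n * p, exp(rnorm(n * p, 4, 0.5))) + 1L, n, p)
  })
  dimnames(m) <- list(paste0("s", seq_len(n)), paste0("f", seq_len(p)))
  m
}

# sparse counts with every row/column observed at least once
sparse_counts <- function(n = 10, p = 16, zero_frac = 0.3, seed = 7) {
  m <- dense_counts(n, p, seed)
  withr::with_seed(seed + 1, {
    drop <- sample(length(m), round(zero_frac * length(m)))
  })
  m[drop] <- 0L
  # keep mask valid
  for (i in seq_len(n)) if (all(m[i, ] == 0)) m[i, 1] <- 5L
  for (j in seq_len(p)) if (all(m[, j] == 0)) m[1, j] <- 5L
  m
}

# small random labeled tree over given tip names
rand_tree <- function(tips, seed = 1) random_tree(tips, seed = seed)

# pocket-sized simulation for module tests (fast)
tiny_config <- function(depth = 5000, ...) {
  sim_config(features_per_block = 10, samples_per_block = 5,
             depth = depth, ...)
}
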