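# Shared fixtures, generated in code.

# Desk-scale-but-small configuration for fast unit tests.
tiny_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_tf = 6, n_targets = 30, layers = 2,
             edges_per_target = 2, replicates = 2,
             protein_length_range = c(40L, 80L), ...)
}

# Hand-built expression dataset: two genotypes over the standard days.
toy_expression <- function(n_genes = 50, n_rep = 3, genotypes = c("A", "B"),
                           days = c(3, 5, 9, 12, 14), sd = 1, seed = 1,
                           shift = 0) {
  set.seed(seed)
  grid <- expand.grid(replicate = seq_len(n_rep), day = days,
                      genotype = genotypes, stringsAsFactors = FALSE)
  grid$sample <- sprintf("%s_d%02d_r%d", grid$genotype, grid$day,
                         grid$replicate)
  vals <- matrix(stats::rnorm(n_genes * nrow(grid), sd = sd), n_genes,
                 dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                 grid$sample))
  vals[, grid$genotype == genotypes[2]] <-
    vals[, grid$genotype == genotypes[2]] + shift
  expression_dataset(vals, grid[, c("sample", "genotype", "day", "replicate")])
}

# Small signed edge table: regulators r*, targets t*.
toy_edges <- function() {
  data.frame(
    regulator = c("r1", "r1", "r2", "r2", "r3"),
    target    = c("t1", "t2", "t2", "t3", "t3"),
    importance = c(0.9, 0.5, 0.4, 0.8, 0.3),
    sign = c(1, 1, -1, 1, -1))
}

# A directed graph as edge list from an adjacency matrix (for LRC oracles).
edges_from_adjacency <- function(adj) {
  idx <- which(adj != 0, arr.ind = TRUE)
  data.frame(regulator = rownames(adj)[idx[, 1]],
             target = colnames(adj)[idx[, 2]])
}

# Brute-force reachability oracle: fraction of other nodes reachable from
# each node by repeated adjacency expansion.
brute_force_lrc <- function(adj) {
  n <- nrow(adj)
  reach <- matrix(FALSE, n, n)
  for (v in seq_len(n)) {
    frontier <- which(adj[v, ] != 0)
    while (length(frontier)) {
      new <- setdiff(frontier, which(reach[v, ]))
      if (!length(new)) break
      reach[v, new] <- TRUE
      frontier <- which(colSums(adj[new, , drop = FALSE] != 0) > 0)
    }
    reach[v, v] <- FALSE
  }
  rowSums(reach) / (n - 1)
}
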