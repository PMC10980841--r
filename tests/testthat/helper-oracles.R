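# Brute-force graph oracles, independent of the package's igraph-based
# predicates, plus small random fixtures used across the tests.

# Connectedness by transitive closure: (I + A)^(n-1) has no zero entry
# iff every node reaches every other.
oracle_connected <- function(adj) {
  n <- nrow(adj)
  if (n == 1L) return(TRUE)
  reach <- diag(n) + adj
  pow <- reach
  for (i in seq_len(n - 2L)) pow <- pow %*% reach
  all(pow > 0)
}

# Two-connectedness by exhaustive single-node removal: connected, >= 3
# nodes, and still connected after deleting any one node.
oracle_two_connected <- function(adj) {
  n <- nrow(adj)
  if (n < 3L || !oracle_connected(adj)) return(FALSE)
  for (v in seq_len(n)) {
    if (!oracle_connected(adj[-v, -v, drop = FALSE])) return(FALSE)
  }
  TRUE
}

random_adjacency <- function(n, p) {
  a <- matrix(0L, n, n)
  ut <- upper.tri(a)
  a[ut] <- rbinom(sum(ut), 1L, p)
  a[lower.tri(a)] <- t(a)[lower.tri(a)]
  a
}

# A symmetric weight matrix with zero diagonal and (almost surely) distinct
# off-diagonal entries.
random_weight_matrix <- function(n) {
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- rnorm(n * (n - 1) / 2)
  w <- w + t(w)
  diag(w) <- 0
  w
}

with_seed_helper <- function(seed, code) withr::with_seed(seed, code)

as_binary_graph <- function(adjacency, density) {
  structure(list(adjacency = adjacency, density = density),
            class = "binary_graph")
}

# Weighted connectome engineered so the nested density sweep is
# disconnected at 0.20 (k = 9: two path components), first connects at
# 0.25 (k = 11: a 10-cycle plus one chord), and that minimally connected
# graph is two-connected. Used to pin down the redundancy-state rule.
cycle_core_weights <- function(jitter_seed = NULL) {
  n <- 10L
  w <- matrix(0, n, n)
  if (!is.null(jitter_seed)) {
    w[upper.tri(w)] <- withr::with_seed(jitter_seed,
                                        runif(sum(upper.tri(w)), -0.4, 0.4))
    w <- w + t(w)
    diag(w) <- 0
  }
  rank_edges <- list(  # strongest first
    c(1, 2), c(2, 3), c(3, 4), c(4, 5),     # path piece one
    c(6, 7), c(7, 8), c(8, 9), c(9, 10),    # path piece two
    c(1, 3),                                # chord inside piece one
    c(5, 6), c(10, 1))                      # closing edges of the 10-cycle
  for (i in seq_along(rank_edges)) {
    e <- rank_edges[[i]]
    w[e[1], e[2]] <- w[e[2], e[1]] <- 2 - 0.05 * i
  }
  w
}
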