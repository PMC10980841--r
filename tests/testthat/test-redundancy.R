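test_that("connectivity predicates agree with brute-force oracles on random graphs", {
  set.seed(31)
  n_checked <- 0
  for (rep in 1:200) {
    n <- sample(4:12, 1)
    adj <- random_adjacency(n, runif(1, 0.1, 0.7))
    expect_identical(is_connected_graph(adj), oracle_connected(adj))
    expect_identical(is_two_connected(adj), oracle_two_connected(adj))
    if (is_two_connected(adj)) expect_true(is_connected_graph(adj))
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 200)
})

test_that("connectivity predicates handle the small fixtures and edge sizes", {
  tg <- toy_graphs()
  expect_true(is_connected_graph(tg$path4$adjacency))
  expect_false(is_two_connected(tg$path4$adjacency))
  expect_true(is_two_connected(tg$cycle4$adjacency))
  expect_false(is_connected_graph(tg$disjoint_edges$adjacency))
  expect_false(is_two_connected(tg$bowtie$adjacency))  # shared node is a cut node

  expect_true(is_connected_graph(matrix(0, 1, 1)))
  two_edge <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_true(is_connected_graph(two_edge))
  expect_false(is_two_connected(two_edge))  # one edge is a single path only
})

test_that("minimal connected density scans the nested stack correctly", {
  tg <- toy_graphs()
  stack <- list(as_binary_graph(tg$disjoint_edges$adjacency, 0.1),
                as_binary_graph(tg$path4$adjacency, 0.2),
                as_binary_graph(tg$cycle4$adjacency + tg$path4$adjacency -
                                  tg$cycle4$adjacency * tg$path4$adjacency, 0.3))
  expect_equal(minimal_connected_density(stack), 0.2)

  never <- list(as_binary_graph(matrix(0L, 4, 4), 0.1),
                as_binary_graph(tg$disjoint_edges$adjacency, 0.2))
  expect_true(is.na(minimal_connected_density(never)))

  connected_first <- list(as_binary_graph(tg$cycle4$adjacency, 0.05))
  expect_equal(minimal_connected_density(connected_first), 0.05)

  non_nested <- list(as_binary_graph(tg$path4$adjacency, 0.1),
                     as_binary_graph(tg$disjoint_edges$adjacency, 0.2))
  expect_error(minimal_connected_density(non_nested), "nested")
})

test_that("redundancy state is 1 only when the minimally connected graph is two-connected", {
  tg <- toy_graphs()
  cyc <- tg$cycle4$adjacency
  path <- tg$path4$adjacency
  disc <- tg$disjoint_edges$adjacency
  full4 <- 1 - diag(4); storage.mode(full4) <- "integer"

  # minimally connected graph is a cycle over all nodes -> 1
  expect_equal(window_redundancy_state(list(
    as_binary_graph(disc, 0.1), as_binary_graph(cyc + disc - cyc * disc, 0.2))), 1L)
  # minimally connected graph is a spanning tree -> 0, even if a denser
  # graph in the stack is two-connected
  expect_equal(window_redundancy_state(list(
    as_binary_graph(path, 0.1), as_binary_graph(full4, 0.5))), 0L)
  # never connected within the grid -> 0
  expect_equal(window_redundancy_state(list(
    as_binary_graph(matrix(0L, 4, 4), 0.1), as_binary_graph(disc, 0.2))), 0L)
})

test_that("engineered weight matrix first connects at 0.25 as a biconnected cycle core", {
  w <- cycle_core_weights()
  graphs <- proportional_binarize(w, density_grid())
  conn <- vapply(graphs, is_connected_graph, logical(1))
  expect_equal(minimal_connected_density(graphs), 0.25)
  expect_false(conn[4])  # 0.20: two path components
  expect_true(conn[5])
  expect_true(is_two_connected(graphs[[5]]))
  expect_equal(window_redundancy_state(graphs), 1L)
})

test_that("redundancy index is the mean of states and validates input", {
  expect_equal(redundancy_index(c(1, 1, 0, 1))$ri_fraction, 0.75)
  expect_equal(redundancy_index(rep(1, 5))$ri_percent, 100)
  expect_equal(redundancy_index(rep(0, 5))$ri_fraction, 0)
  expect_error(redundancy_index(integer(0)), "nonempty")
  expect_error(redundancy_index(c(0, 2)), "0/1")
})

test_that("connectedness is monotone in density across random nested stacks", {
  set.seed(55)
  for (rep in 1:20) {
    graphs <- proportional_binarize(random_weight_matrix(14), density_grid())
    conn <- vapply(graphs, is_connected_graph, logical(1))
    expect_true(all(diff(conn) >= 0))
  }
})

test_that("RI lies in [0, 1] and is invariant to node relabelling", {
  model <- cov_model(16, block_sizes = c(8, 8), within_block_corr = 0.6,
                     between_block_corr = 0.15, noise_sd = 1)
  spec <- window_spec(20, 4)
  for (s in 1:5) {
    ts <- simulate_timeseries(model, 60, seed = 100 + s)
    prof <- compute_ri(ts, spec)
    expect_gte(prof$ri_fraction, 0)
    expect_lte(prof$ri_fraction, 1)
    perm <- sample(16)
    ts_perm <- redconn:::new_ts_matrix(ts$values[, perm], ts$tr_seconds,
                                       ts$region_labels[perm])
    expect_equal(compute_ri(ts_perm, spec)$ri_fraction, prof$ri_fraction)
    expect_equal(length(prof$states), nrow(enumerate_windows(60, spec)))
  }
})

test_that("window-length sweep returns one profile per length", {
  ts <- simulate_timeseries(cov_model(12, noise_sd = 0.8), 70, seed = 8)
  sweep <- ri_sweep(ts, lengths = c(20, 30), step = 5)
  expect_named(sweep, c("L20", "L30"))
  for (p in sweep) expect_s3_class(p, "redundancy_profile")
})
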