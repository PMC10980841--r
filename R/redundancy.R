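#' Is a binary graph connected?
#'
#' A graph is connected when a path exists between each pair of nodes and
#' there are no isolated nodes (a single traversal from any node reaches all
#' nodes). A one-node graph is connected; an empty-edge graph on >= 2 nodes
#' is not.
#'
#' @param g a \code{binary_graph} or 0/1 adjacency matrix.
#' @export
is_connected_graph <- function(g) {
  adj <- graph_adjacency(g)
  n <- nrow(adj)
  if (n == 1L) return(TRUE)
  ig <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::is_connected(ig)
}

#' Is a binary graph two-connected (biconnected)?
#'
#' True when the graph is connected, has at least three nodes, and has no
#' articulation point, so every pair of nodes is joined by at least two
#' paths sharing no node other than their endpoints. A two-node graph is
#' not two-connected: a single edge provides only one path.
#'
#' @param g a \code{binary_graph} or 0/1 adjacency matrix.
#' @export
is_two_connected <- function(g) {
  adj <- graph_adjacency(g)
  n <- nrow(adj)
  if (n < 3L) return(FALSE)
  ig <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::is_connected(ig) && length(igraph::articulation_points(ig)) == 0L
}

graph_adjacency <- function(g) {
  adj <- if (inherits(g, "binary_graph")) g$adjacency else g
  assert_symmetric_binary(adj)
  storage.mode(adj) <- "double"
  adj
}

check_nested <- function(graphs) {
  stopifnot(is.list(graphs), length(graphs) >= 1,
            all(vapply(graphs, inherits, logical(1), "binary_graph")))
  dens <- vapply(graphs, `[[`, numeric(1), "density")
  if (any(diff(dens) <= 0)) {
    stop("graphs must be ordered by strictly increasing density", call. = FALSE)
  }
  for (i in seq_len(length(graphs) - 1L)) {
    if (any(graphs[[i]]$adjacency > graphs[[i + 1L]]$adjacency)) {
      stop("graphs are not nested: an edge present at a lower density is missing at a higher one",
           call. = FALSE)
    }
  }
  invisible(dens)
}

#' Minimal connected density of a nested graph stack
#'
#' Scans a density-ordered, nested stack of binary graphs and returns the
#' smallest grid density at which the graph is connected, or \code{NA} if
#' the network never connects within the grid.
#'
#' @param graphs list of \code{binary_graph}, nested and density-ordered
#'   (as produced by \code{\link{proportional_binarize}}).
#' @export
minimal_connected_density <- function(graphs) {
  dens <- check_nested(graphs)
  for (i in seq_along(graphs)) {
    if (is_connected_graph(graphs[[i]])) return(dens[[i]])
  }
  NA_real_
}

#' Redundancy state of one sliding window
#'
#' Assigns 1 when the minimally connected network — the lowest-density
#' thresholded graph in the sweep that is connected — is also two-connected,
#' and 0 otherwise. Two-connectedness is evaluated only at the minimal
#' connected density; a network that never connects within the grid gets
#' state 0 (it cannot be two-connected if it cannot even connect).
#'
#' @param graphs nested, density-ordered list of \code{binary_graph}.
#' @return integer 0 or 1.
#' @export
window_redundancy_state <- function(graphs) {
  dens <- check_nested(graphs)
  for (i in seq_along(graphs)) {
    if (is_connected_graph(graphs[[i]])) {
      return(as.integer(is_two_connected(graphs[[i]])))
    }
  }
  0L
}

#' Redundancy index from per-window states
#'
#' The redundancy index (RI) is the occurrence probability of the state-1
#' windows: the fraction of sliding windows whose minimally connected
#' network is also two-connected.
#'
#' @param states vector of 0/1 per-window states.
#' @param minimal_densities optional per-window minimal connected densities
#'   (NA where never connected), carried into the profile.
#' @return a \code{redundancy_profile}: list with \code{states},
#'   \code{minimal_connected_density}, \code{ri_fraction}, \code{ri_percent}.
#' @export
redundancy_index <- function(states, minimal_densities = NULL) {
  if (length(states) == 0) stop("`states` must be nonempty", call. = FALSE)
  if (!all(states %in% c(0, 1))) stop("`states` must be 0/1", call. = FALSE)
  ri <- mean(states)
  structure(
    list(states = as.integer(states),
         minimal_connected_density = minimal_densities,
         ri_fraction = ri, ri_percent = 100 * ri),
    class = "redundancy_profile")
}

#' @export
print.redundancy_profile <- function(x, ...) {
  cat(sprintf("Redundancy profile: %d windows, RI = %.1f%% (%d two-connected-at-minimum)\n",
              length(x$states), x$ri_percent, sum(x$states)))
  invisible(x)
}

#' Subject-level redundancy index from a parcellated time series
#'
#' Full per-subject pipeline: enumerate sliding windows, compute each
#' window's Fisher-z connectome, binarize across the density grid, assign
#' the per-window redundancy state, and average states into RI.
#'
#' @param ts a \code{ts_matrix}.
#' @param spec a \code{\link{window_spec}} (default 30 volumes, step 1).
#' @param grid a \code{\link{density_grid}} (default 5--50\% in 5\% steps).
#' @param ranking,rounding passed to \code{\link{proportional_binarize}}.
#' @return a \code{redundancy_profile} with per-window states and minimal
#'   connected densities.
#' @export
compute_ri <- function(ts, spec = window_spec(), grid = density_grid(),
                       ranking = "signed", rounding = "round") {
  stopifnot(inherits(ts, "ts_matrix"))
  wins <- enumerate_windows(nrow(ts$values), spec)
  n_win <- nrow(wins)
  states <- integer(n_win)
  mcd <- rep(NA_real_, n_win)
  for (i in seq_len(n_win)) {
    w <- window_connectome(ts, wins[i, ], window_index = i)
    graphs <- proportional_binarize(w, grid, ranking = ranking,
                                    rounding = rounding)
    mcd[i] <- minimal_connected_density(graphs)
    if (!is.na(mcd[i])) {
      g <- graphs[[match(mcd[i], grid$densities)]]
      states[i] <- as.integer(is_two_connected(g))
    }
  }
  prof <- redundancy_index(states, minimal_densities = mcd)
  prof$window_spec <- spec
  prof$density_grid <- grid$densities
  prof
}

#' Redundancy index across several window lengths
#'
#' Recomputes RI at alternative window lengths (default 30, 40 and 50
#' volumes) to check robustness of the index to the window-length choice.
#'
#' @param ts a \code{ts_matrix}.
#' @param lengths window lengths in volumes.
#' @param step step size in volumes.
#' @param grid a \code{\link{density_grid}}.
#' @param ... passed to \code{\link{compute_ri}}.
#' @return named list of \code{redundancy_profile}, one per length.
#' @export
ri_sweep <- function(ts, lengths = c(30, 40, 50), step = 1,
                     grid = density_grid(), ...) {
  res <- lapply(lengths, function(L) {
    compute_ri(ts, window_spec(L, step), grid, ...)
  })
  names(res) <- paste0("L", lengths)
  res
}
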