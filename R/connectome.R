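#' Sliding-window specification
#'
#' @param length_volumes window length in volumes (default 30, i.e. 60 s at
#'   TR = 2 s).
#' @param step_volumes step between consecutive window starts (default 1
#'   volume, giving a 58 s overlap between consecutive 30-volume windows at
#'   TR = 2 s).
#' @export
window_spec <- function(length_volumes = 30, step_volumes = 1) {
  length_volumes <- assert_count(length_volumes, "length_volumes")
  step_volumes <- assert_count(step_volumes, "step_volumes")
  if (step_volumes > length_volumes) {
    stop("`step_volumes` must not exceed `length_volumes`", call. = FALSE)
  }
  structure(list(length_volumes = length_volumes, step_volumes = step_volumes),
            class = "window_spec")
}

#' Enumerate sliding-window intervals
#'
#' Returns 0-based half-open volume intervals [t, t + L) for
#' t = 0, step, 2 step, ... while t + L <= n_volumes. The number of windows
#' is floor((n_volumes - L) / step) + 1.
#'
#' @param n_volumes total number of volumes in the series.
#' @param spec a \code{\link{window_spec}}.
#' @return integer matrix with columns \code{start}, \code{end} (half-open).
#' @export
enumerate_windows <- function(n_volumes, spec) {
  n_volumes <- assert_count(n_volumes, "n_volumes")
  stopifnot(inherits(spec, "window_spec"))
  L <- spec$length_volumes
  if (L > n_volumes) {
    stop(sprintf("window length (%d volumes) exceeds series length (%d volumes)",
                 L, n_volumes), call. = FALSE)
  }
  starts <- seq.int(0L, n_volumes - L, by = spec$step_volumes)
  cbind(start = starts, end = starts + L)
}

#' Temporal overlap of consecutive windows, in seconds
#'
#' @param spec a \code{\link{window_spec}}.
#' @param tr_seconds repetition time in seconds.
#' @export
window_overlap_seconds <- function(spec, tr_seconds) {
  stopifnot(inherits(spec, "window_spec"), tr_seconds > 0)
  (spec$length_volumes - spec$step_volumes) * tr_seconds
}

#' Density grid for proportional thresholding
#'
#' Default is the 5\%--50\% range in 5\% increments, yielding 10 binary
#' networks per sliding window; the upper bound avoids saturation of the
#' connectivity metrics at high densities.
#'
#' @param densities strictly increasing fractions in (0, 1].
#' @export
density_grid <- function(densities = seq(0.05, 0.50, by = 0.05)) {
  stopifnot(is.numeric(densities), length(densities) >= 1,
            all(densities > 0), all(densities <= 1))
  if (any(diff(densities) <= 0)) {
    stop("`densities` must be strictly increasing", call. = FALSE)
  }
  structure(list(densities = as.numeric(densities)), class = "density_grid")
}

#' Per-window weighted connectome (Fisher-z correlation matrix)
#'
#' Computes the Pearson correlation between the BOLD time courses of every
#' pair of regions within the window and applies the Fisher r-to-z transform
#' z = atanh(r). Perfect correlations (|r| = 1, possible only in degenerate
#' windows) are capped at 1 - cap_eps before the transform: downstream
#' proportional thresholding only uses ranks, so the cap is inconsequential.
#'
#' @param ts a \code{ts_matrix}.
#' @param interval length-2 vector: 0-based half-open [start, end), as
#'   produced by \code{\link{enumerate_windows}}; rows of one matrix row.
#' @param window_index index recorded in the result (for diagnostics).
#' @param cap_eps cap tolerance for |r| = 1 (default 1e-7).
#' @return a \code{weighted_connectome}: list with symmetric \code{z_matrix}
#'   (zero diagonal) and \code{window_index}.
#' @export
window_connectome <- function(ts, interval, window_index = NA_integer_,
                              cap_eps = 1e-7) {
  stopifnot(inherits(ts, "ts_matrix"), length(interval) == 2)
  start <- interval[[1]]; end <- interval[[2]]
  n_vol <- nrow(ts$values)
  if (start < 0 || end > n_vol || end - start < 2) {
    stop("interval out of range for the time series", call. = FALSE)
  }
  sub <- ts$values[(start + 1L):end, , drop = FALSE]
  sds <- apply(sub, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- ts$region_labels[sds == 0]
    stop(sprintf("zero-variance region(s) %s in window %s",
                 paste(bad, collapse = ", "),
                 ifelse(is.na(window_index), sprintf("[%d,%d)", start, end),
                        as.character(window_index))), call. = FALSE)
  }
  r <- stats::cor(sub)
  r[r > 1 - cap_eps] <- 1 - cap_eps
  r[r < -(1 - cap_eps)] <- -(1 - cap_eps)
  z <- atanh(r)
  diag(z) <- 0
  z <- (z + t(z)) / 2  # enforce exact symmetry against floating-point asymmetry
  structure(list(z_matrix = z, window_index = window_index),
            class = "weighted_connectome")
}

# Number of retained edges at density d among E possible edges. Half-up
# rounding (not banker's) so k is deterministic at exact .5 boundaries.
density_edge_count <- function(d, n_edges,
                               rounding = c("round", "floor", "ceiling")) {
  rounding <- match.arg(rounding)
  x <- d * n_edges
  switch(rounding,
         round = floor(x + 0.5),
         floor = floor(x),
         ceiling = ceiling(x))
}

#' Proportional (density) thresholding of a weighted connectome
#'
#' For each density d on the grid, retains the k(d) = round(d N(N-1)/2)
#' strongest edges and returns the corresponding binary graph. A single
#' deterministic edge ranking is used for all densities — by signed weight
#' (strongest positive first; the common convention) or by absolute weight,
#' with ties broken by lexicographic node-pair order — so the resulting
#' graphs are nested: the edge set at a lower density is a subset of the
#' edge set at any higher density. Because atanh is strictly increasing,
#' thresholding the raw correlation matrix and the Fisher-z matrix gives
#' identical graphs.
#'
#' @param w a \code{weighted_connectome} or a symmetric weight matrix.
#' @param grid a \code{\link{density_grid}}.
#' @param ranking edge ranking mode: "signed" (default) or "absolute".
#' @param rounding rule for k(d): "round" (half-up, default), "floor",
#'   "ceiling".
#' @return list of \code{binary_graph} objects (fields \code{adjacency},
#'   \code{density}), one per grid density, in grid order.
#' @export
proportional_binarize <- function(w, grid = density_grid(),
                                  ranking = c("signed", "absolute"),
                                  rounding = c("round", "floor", "ceiling")) {
  ranking <- match.arg(ranking)
  rounding <- match.arg(rounding)
  stopifnot(inherits(grid, "density_grid"))
  zm <- if (inherits(w, "weighted_connectome")) w$z_matrix else w
  stopifnot(is.matrix(zm), nrow(zm) == ncol(zm))
  n <- nrow(zm)
  ut <- which(upper.tri(zm), arr.ind = TRUE)
  wt <- zm[upper.tri(zm)]
  key <- if (ranking == "absolute") abs(wt) else wt
  # order by decreasing weight, ties by (i, j) lexicographic
  ord <- order(-key, ut[, 1], ut[, 2])
  n_edges <- length(wt)
  lapply(grid$densities, function(d) {
    k <- density_edge_count(d, n_edges, rounding)
    adj <- matrix(0L, n, n)
    if (k > 0) {
      keep <- ord[seq_len(min(k, n_edges))]
      adj[cbind(ut[keep, 1], ut[keep, 2])] <- 1L
      adj[cbind(ut[keep, 2], ut[keep, 1])] <- 1L
    }
    dimnames(adj) <- dimnames(zm)
    structure(list(adjacency = adj, density = d), class = "binary_graph")
  })
}
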