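# Internal helpers shared across modules.

# Evaluate `code` under a given RNG seed, restoring the caller's RNG state
# afterwards so no generator leaks global random state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != floor(x) || x < min) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

assert_symmetric_binary <- function(adj) {
  if (!is.matrix(adj) || nrow(adj) != ncol(adj)) {
    stop("adjacency must be a square matrix", call. = FALSE)
  }
  if (any(adj != 0 & adj != 1)) stop("adjacency must be 0/1", call. = FALSE)
  if (any(adj != t(adj))) stop("adjacency must be symmetric", call. = FALSE)
  if (any(diag(adj) != 0)) stop("adjacency must have a zero diagonal", call. = FALSE)
  invisible(adj)
}

# Column z-scoring of a data frame restricted to `cols`; binary/ordinal
# columns are standardized like continuous ones so coefficients stay
# comparable.
zscore_columns <- function(table, cols) {
  for (cl in cols) {
    table[[cl]] <- zscore(table[[cl]])
  }
  table
}
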