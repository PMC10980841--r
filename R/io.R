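#' Read a parcellated time-series matrix from delimited text
#'
#' Expects a rectangular numeric body (rows = volumes, columns = regions)
#' under a one-line header of region labels. The delimiter is auto-detected
#' (tab or comma). Ragged rows and non-numeric cells are rejected with
#' their line numbers.
#'
#' @param path file path.
#' @param tr_seconds repetition time in seconds (supplied separately; it is
#'   not stored in the file).
#' @return a \code{ts_matrix}.
#' @export
read_timeseries <- function(path, tr_seconds = 2) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  counts <- utils::count.fields(path, sep = sep, quote = "")
  if (length(unique(counts)) > 1L) {
    bad <- which(counts != counts[1L])
    stop(sprintf("ragged row(s) at line(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                           colClasses = "character", check.names = FALSE)
  chr <- as.matrix(raw)
  mat <- suppressWarnings(matrix(as.numeric(chr), nrow = nrow(chr),
                                 ncol = ncol(chr)))
  colnames(mat) <- colnames(raw)
  if (anyNA(mat)) {
    bad_lines <- unique(which(rowSums(is.na(mat)) > 0)) + 1L  # +1 for header
    stop(sprintf("non-numeric cell(s) at line(s): %s",
                 paste(bad_lines, collapse = ", ")), call. = FALSE)
  }
  if (ncol(mat) < 3L) {
    stop("time series must contain at least 3 regions", call. = FALSE)
  }
  new_ts_matrix(mat, tr_seconds, colnames(raw))
}

#' Write a time-series matrix as tab-delimited text
#'
#' @param ts a \code{ts_matrix}.
#' @param path output path.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "ts_matrix"))
  utils::write.table(ts$values, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = ts$region_labels)
  invisible(path)
}

#' Read / write a cohort table (CSV)
#'
#' @param path file path.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname read_cohort
#' @param table cohort data frame.
#' @export
write_cohort <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a per-subject redundancy profile as JSON
#'
#' @param profile a \code{redundancy_profile}.
#' @param path output path.
#' @param subject_id identifier recorded in the JSON.
#' @export
write_ri_profile <- function(profile, path, subject_id = NA_character_) {
  stopifnot(inherits(profile, "redundancy_profile"))
  obj <- list(
    subject_id = subject_id,
    window_spec = if (!is.null(profile$window_spec)) {
      list(length_volumes = profile$window_spec$length_volumes,
           step_volumes = profile$window_spec$step_volumes)
    } else NULL,
    density_grid = profile$density_grid,
    states = profile$states,
    minimal_connected_density = profile$minimal_connected_density,
    ri_fraction = profile$ri_fraction,
    ri_percent = profile$ri_percent)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Default run configuration
#'
#' A flat, YAML-serializable list of every tunable of the RI pipeline and
#' the statistical layer; \code{\link{write_run_config}} and
#' \code{\link{read_run_config}} round-trip it losslessly so each run can
#' emit its resolved configuration.
#'
#' @export
default_run_config <- function() {
  list(
    window_length_volumes = 30L,
    window_step_volumes = 1L,
    tr_seconds = 2,
    density_start = 0.05, density_stop = 0.50, density_step = 0.05,
    edge_ranking = "signed",
    k_rounding = "round",
    stepwise_p_enter = 0.05, stepwise_p_remove = 0.10,
    cv_folds = 10L,
    n_boot = 5000L,
    bootstrap_ci = "percentile",
    seed = 1L)
}

#' @rdname default_run_config
#' @param config configuration list.
#' @param path YAML path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname default_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- default_run_config()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  utils::modifyList(defaults, cfg)
}

#' Density grid from a run configuration
#'
#' @param config configuration list.
#' @export
config_density_grid <- function(config) {
  density_grid(seq(config$density_start, config$density_stop,
                   by = config$density_step))
}
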