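#' Block-constant covariance model for synthetic parcellated BOLD series
#'
#' Describes a multivariate normal generative family in which regions fall
#' into communities (blocks): every pair of regions within a block shares
#' correlation \code{within_block_corr}, every pair across blocks shares
#' \code{between_block_corr}, and independent Gaussian measurement noise of
#' standard deviation \code{noise_sd} is added on top of the unit-variance
#' signal. This is the simplest structure under which a density sweep of
#' thresholded graphs produces both tree-like and cycle-rich minimally
#' connected networks, which is what the redundancy pipeline needs to be
#' exercised on.
#'
#' @param n_regions number of regions (columns of the simulated series).
#' @param block_sizes integer vector partitioning the regions; must sum to
#'   \code{n_regions}.
#' @param within_block_corr signal correlation within a block, in [0, 1).
#' @param between_block_corr signal correlation between blocks, in [0, 1);
#'   must not exceed \code{within_block_corr}.
#' @param noise_sd standard deviation of the added independent noise
#'   (the signal has unit variance, so the observed correlation between two
#'   regions with signal correlation r is r / (1 + noise_sd^2)).
#' @return an object of class \code{cov_model}.
#' @export
cov_model <- function(n_regions, block_sizes = n_regions,
                      within_block_corr = 0.5, between_block_corr = 0.1,
                      noise_sd = 1) {
  n_regions <- assert_count(n_regions, "n_regions", min = 1L)
  block_sizes <- vapply(block_sizes, assert_count, integer(1), name = "block_sizes")
  if (sum(block_sizes) != n_regions) {
    stop("`block_sizes` must sum to `n_regions`", call. = FALSE)
  }
  stopifnot(within_block_corr >= 0, within_block_corr < 1,
            between_block_corr >= 0, between_block_corr < 1,
            noise_sd >= 0)
  if (between_block_corr > within_block_corr) {
    stop("`between_block_corr` must not exceed `within_block_corr`", call. = FALSE)
  }
  sigma <- matrix(between_block_corr, n_regions, n_regions)
  stop_idx <- cumsum(block_sizes)
  start_idx <- c(1L, utils::head(stop_idx, -1L) + 1L)
  for (b in seq_along(block_sizes)) {
    idx <- start_idx[b]:stop_idx[b]
    sigma[idx, idx] <- within_block_corr
  }
  diag(sigma) <- 1
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop(sprintf(
      "implied signal covariance is not positive semi-definite (min eigenvalue %.3g)",
      min(ev)), call. = FALSE)
  }
  structure(
    list(n_regions = n_regions, block_sizes = block_sizes,
         within_block_corr = within_block_corr,
         between_block_corr = between_block_corr,
         noise_sd = noise_sd, sigma = sigma),
    class = "cov_model")
}

#' Simulate a parcellated BOLD time-series matrix
#'
#' Draws \code{n_volumes} zero-mean multivariate normal samples with the
#' model's block covariance and adds independent Gaussian noise. The same
#' seed always reproduces the same matrix; the caller's RNG state is left
#' untouched.
#'
#' @param model a \code{\link{cov_model}}.
#' @param n_volumes number of time points (>= 2).
#' @param seed integer seed governing all randomness of this call.
#' @param tr_seconds repetition time in seconds (default 2, a typical fMRI TR).
#' @param region_labels optional character vector of region names.
#' @return a \code{ts_matrix}: list with \code{values} (n_volumes x n_regions
#'   matrix), \code{tr_seconds}, \code{region_labels}.
#' @export
simulate_timeseries <- function(model, n_volumes, seed, tr_seconds = 2,
                                region_labels = NULL) {
  stopifnot(inherits(model, "cov_model"))
  n_volumes <- assert_count(n_volumes, "n_volumes", min = 2L)
  p <- model$n_regions
  if (is.null(region_labels)) {
    region_labels <- sprintf("R%03d", seq_len(p))
  }
  stopifnot(length(region_labels) == p)
  # chol() of a PSD-but-singular matrix can fail; regularize negligibly.
  ch <- chol(model$sigma + diag(1e-10, p))
  values <- with_seed(seed, {
    z <- matrix(stats::rnorm(n_volumes * p), n_volumes, p)
    signal <- z %*% ch
    noise <- if (model$noise_sd > 0) {
      matrix(stats::rnorm(n_volumes * p, sd = model$noise_sd), n_volumes, p)
    } else 0
    signal + noise
  })
  colnames(values) <- region_labels
  new_ts_matrix(values, tr_seconds, region_labels)
}

new_ts_matrix <- function(values, tr_seconds, region_labels) {
  stopifnot(is.matrix(values), all(is.finite(values)), tr_seconds > 0)
  structure(
    list(values = values, tr_seconds = tr_seconds,
         region_labels = region_labels),
    class = "ts_matrix")
}

#' @export
print.ts_matrix <- function(x, ...) {
  cat(sprintf("Parcellated time series: %d volumes x %d regions (TR = %g s)\n",
              nrow(x$values), ncol(x$values), x$tr_seconds))
  invisible(x)
}

#' Ground-truth path coefficients for a simple mediation model
#'
#' Holds the generative coefficients of the X -> M -> Y system: \code{a}
#' (effect of X on M), \code{b} (effect of M on Y given X), and \code{c_prime}
#' (direct effect of X on Y). The total effect is \code{c = c_prime + a * b}.
#'
#' @param a_path,b_path,c_prime path coefficients.
#' @param noise_m_sd,noise_y_sd residual standard deviations of M and Y.
#' @param x_kind "binary" (Bernoulli exposure, e.g. microbleed presence) or
#'   "continuous" (standard normal exposure, e.g. a reserve score).
#' @export
mediation_truth <- function(a_path = 0.5, b_path = 0.4, c_prime = 0.2,
                            noise_m_sd = 1, noise_y_sd = 1,
                            x_kind = c("binary", "continuous")) {
  x_kind <- match.arg(x_kind)
  stopifnot(noise_m_sd >= 0, noise_y_sd >= 0)
  structure(
    list(a_path = a_path, b_path = b_path, c_prime = c_prime,
         noise_m_sd = noise_m_sd, noise_y_sd = noise_y_sd, x_kind = x_kind),
    class = "mediation_truth")
}

#' Simulate a subject-level cohort table with known mediation ground truth
#'
#' Generates a table shaped like a community-cohort characteristics table:
#' demographics (age, sex, years of education), head motion (mean framewise
#' displacement), vascular risk indicators, small-vessel-disease markers,
#' cognitive-reserve scores, cognitive-domain z-scores, and a redundancy-index
#' column. The exposure X (one of the schema columns, by default microbleed
#' presence), the mediator M (by default \code{ri_percent}) and the outcome Y
#' (by default \code{memory_z}) follow the linear system
#' \deqn{M = a X + \gamma_M' Z + e_M, \quad Y = c' X + b M + \gamma_Y' Z + e_Y}
#' where Z are z-scored age/sex/education covariates, so downstream
#' regression and mediation estimates can be checked against known truth.
#' The mediator and outcome are kept on their generative (z-like) scale.
#'
#' @param n_subjects number of subjects (>= 10).
#' @param truth a \code{\link{mediation_truth}}.
#' @param seed integer seed for all randomness of this call.
#' @param x_col,m_col,y_col schema columns to carry X, M and Y.
#' @param prevalence Bernoulli prevalence when \code{truth$x_kind} is
#'   "binary" (default 0.10, an unbalanced exposure such as microbleeds).
#' @param cov_effects_m,cov_effects_y named coefficients of the z-scored
#'   age/sex/education covariates in the M and Y equations.
#' @return data frame with one row per subject; the generative truth is
#'   attached as attribute \code{"truth"}.
#' @export
simulate_cohort <- function(n_subjects, truth = mediation_truth(), seed,
                            x_col = "mbs_present", m_col = "ri_percent",
                            y_col = "memory_z", prevalence = 0.10,
                            cov_effects_m = c(age = -0.1, sex = 0.05, education = 0.1),
                            cov_effects_y = c(age = -0.15, sex = 0.05, education = 0.15)) {
  n_subjects <- assert_count(n_subjects, "n_subjects", min = 10L)
  stopifnot(inherits(truth, "mediation_truth"),
            prevalence > 0, prevalence < 1)
  with_seed(seed, {
    n <- n_subjects
    tab <- data.frame(
      subject_id = sprintf("S%04d", seq_len(n)),
      age = stats::rnorm(n, mean = 58, sd = 6),
      sex = stats::rbinom(n, 1L, 0.57),
      education = pmax(round(stats::rnorm(n, mean = 9, sd = 3)), 0),
      mean_fd = round(exp(stats::rnorm(n, log(0.11), 0.3)), 3),
      smoking = stats::rbinom(n, 1L, 0.273),
      hypertension = stats::rbinom(n, 1L, 0.405),
      diabetes = stats::rbinom(n, 1L, 0.091),
      hyperlipidemia = stats::rbinom(n, 1L, 0.174),
      hyperhomocysteinemia = stats::rbinom(n, 1L, 0.322),
      lacunes_present = stats::rbinom(n, 1L, 0.099),
      mbs_present = stats::rbinom(n, 1L, 0.099),
      dwpvs = sample(0:4, n, replace = TRUE, prob = c(0.1, 0.45, 0.3, 0.1, 0.05)),
      bgpvs = sample(0:4, n, replace = TRUE, prob = c(0.15, 0.6, 0.15, 0.07, 0.03)),
      fazekas_peri = sample(0:3, n, replace = TRUE, prob = c(0.35, 0.45, 0.15, 0.05)),
      fazekas_deep = sample(0:3, n, replace = TRUE, prob = c(0.2, 0.6, 0.15, 0.05)),
      cri_education = stats::rnorm(n, 90.5, 2.7),
      cri_work = stats::rnorm(n, 100, 15),
      cri_leisure = stats::rnorm(n, 79, 10),
      stringsAsFactors = FALSE)
    tab$cri_total <- rowMeans(tab[, c("cri_education", "cri_work", "cri_leisure")]) +
      stats::rnorm(n, 0, 3)
    tab$svd_total <- pmin(
      tab$lacunes_present + tab$mbs_present +
        as.integer(tab$bgpvs >= 2) + as.integer(tab$fazekas_peri >= 3 | tab$fazekas_deep >= 2),
      4L)

    # Exposure column: overwrite the designated schema column with X drawn
    # per the truth, so the mediation system is exactly linear in it.
    x <- if (truth$x_kind == "binary") {
      stats::rbinom(n, 1L, prevalence)
    } else {
      stats::rnorm(n)
    }
    tab[[x_col]] <- x

    covs <- cbind(age = zscore(tab$age), sex = zscore(tab$sex),
                  education = zscore(tab$education))
    lin_m <- drop(covs[, names(cov_effects_m), drop = FALSE] %*% cov_effects_m)
    lin_y <- drop(covs[, names(cov_effects_y), drop = FALSE] %*% cov_effects_y)
    m <- truth$a_path * x + lin_m +
      if (truth$noise_m_sd > 0) stats::rnorm(n, sd = truth$noise_m_sd) else 0
    y <- truth$c_prime * x + truth$b_path * m + lin_y +
      if (truth$noise_y_sd > 0) stats::rnorm(n, sd = truth$noise_y_sd) else 0
    tab[[m_col]] <- m
    tab[[y_col]] <- y

    # Remaining cognitive-domain composites: correlated noise, no X/M effect.
    for (dom in c("language_z", "processing_speed_z", "executive_z", "attention_z")) {
      if (!dom %in% names(tab)) tab[[dom]] <- zscore(lin_y + stats::rnorm(n))
    }
    if (!"memory_z" %in% names(tab)) tab$memory_z <- zscore(lin_y + stats::rnorm(n))
    tab$global_cognition_z <- zscore(rowMeans(
      tab[, c("memory_z", "language_z", "processing_speed_z", "executive_z", "attention_z")]))
    attr(tab, "truth") <- truth
    tab
  })
}

#' Labelled toy graphs with known connectivity class
#'
#' Small fixtures covering the three regimes the redundancy state
#' distinguishes: disconnected; connected but not two-connected (a path, and
#' a graph with an internal cut node joining two triangles); and
#' two-connected (a cycle).
#'
#' @return named list; each element has \code{adjacency} (0/1 matrix) and
#'   \code{class} (one of "disconnected", "connected_not_two_connected",
#'   "two_connected").
#' @export
toy_graphs <- function() {
  adj_from_edges <- function(n, edges) {
    a <- matrix(0L, n, n)
    for (e in edges) {
      a[e[1], e[2]] <- 1L
      a[e[2], e[1]] <- 1L
    }
    a
  }
  list(
    disjoint_edges = list(
      adjacency = adj_from_edges(4, list(c(1, 2), c(3, 4))),
      class = "disconnected"),
    path4 = list(
      adjacency = adj_from_edges(4, list(c(1, 2), c(2, 3), c(3, 4))),
      class = "connected_not_two_connected"),
    bowtie = list(  # two triangles sharing a cut node
      adjacency = adj_from_edges(5, list(c(1, 2), c(2, 3), c(1, 3),
                                         c(3, 4), c(4, 5), c(3, 5))),
      class = "connected_not_two_connected"),
    cycle4 = list(
      adjacency = adj_from_edges(4, list(c(1, 2), c(2, 3), c(3, 4), c(4, 1))),
      class = "two_connected")
  )
}
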