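#' Standardize a numeric vector to z-scores
#'
#' Centers to mean 0 and scales to sample standard deviation 1.
#'
#' @param x numeric vector with positive standard deviation.
#' @export
zscore <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  s <- stats::sd(x)
  if (s == 0) stop("cannot z-score a constant column", call. = FALSE)
  (x - mean(x)) / s
}

#' Benjamini-Hochberg adjustment of p-values
#'
#' Step-up false-discovery-rate control; adjusted values are monotone in the
#' raw p-values, never smaller than them, and capped at 1.
#'
#' @param p_values vector of p-values in [0, 1].
#' @export
bh_adjust <- function(p_values) {
  stopifnot(is.numeric(p_values), length(p_values) >= 1)
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

check_model_columns <- function(table, cols) {
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols)) {
    stop(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  for (cl in cols) {
    v <- table[[cl]]
    if (!is.numeric(v)) stop(sprintf("column `%s` is not numeric", cl), call. = FALSE)
    if (anyNA(v) || any(!is.finite(v))) {
      stop(sprintf("column `%s` contains missing or non-finite values", cl),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Standardized linear regression with covariates
#'
#' Ordinary least squares on z-scored outcome and z-scored predictors and
#' covariates (binary columns standardized too), so coefficients are
#' standardized betas comparable across predictors: in a simple regression
#' the beta equals the Pearson correlation of outcome and predictor.
#'
#' @param table cohort data frame.
#' @param outcome,predictors,covariates column names; covariates enter the
#'   model but are reported with role "covariate".
#' @param standardize if FALSE, fit on the raw scale (coefficients are then
#'   unstandardized).
#' @return a \code{std_lm}: list with \code{coefficients} (term, beta, se,
#'   p, ci_low, ci_high, vif, role), \code{adj_r_squared}, \code{mse}, and
#'   the underlying \code{fit}.
#' @export
fit_standardized_lm <- function(table, outcome, predictors,
                                covariates = character(),
                                standardize = TRUE) {
  rhs <- c(predictors, covariates)
  stopifnot(length(rhs) >= 1)
  cols <- c(outcome, rhs)
  check_model_columns(table, cols)
  df <- as.data.frame(table)[, cols, drop = FALSE]
  if (standardize) df <- zscore_columns(df, cols)
  n <- nrow(df)
  if (n <= length(rhs) + 1L) {
    stop("more coefficients than observations", call. = FALSE)
  }
  fit <- stats::lm(stats::reformulate(rhs, response = outcome), data = df)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop(sprintf("rank-deficient design; collinear column(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  ci <- stats::confint(fit)
  vifs <- if (length(rhs) >= 2) car::vif(fit) else stats::setNames(1, rhs)
  terms_out <- rhs
  res <- data.frame(
    term = terms_out,
    beta = ct[terms_out, "Estimate"],
    se = ct[terms_out, "Std. Error"],
    p = ct[terms_out, "Pr(>|t|)"],
    ci_low = ci[terms_out, 1],
    ci_high = ci[terms_out, 2],
    vif = as.numeric(vifs[terms_out]),
    role = ifelse(terms_out %in% predictors, "predictor", "covariate"),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(
    list(coefficients = res,
         adj_r_squared = sm$adj.r.squared,
         mse = mean(stats::residuals(fit)^2),
         outcome = outcome, predictors = predictors, covariates = covariates,
         fit = fit),
    class = "std_lm")
}

#' @export
print.std_lm <- function(x, ...) {
  cat(sprintf("Standardized OLS: %s ~ %s (adj R^2 = %.4f, MSE = %.4f)\n",
              x$outcome, paste(c(x$predictors, x$covariates), collapse = " + "),
              x$adj_r_squared, x$mse))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' One-predictor-at-a-time regression grid with per-outcome FDR control
#'
#' Fits each outcome on each predictor (plus covariates) separately and
#' adjusts the predictor p-values with Benjamini-Hochberg within each
#' outcome family — the FDR is controlled within each cognitive domain, not
#' across all tests. The covariate set can be reduced for chosen predictors
#' (e.g. only age and sex when a predictor already encodes education).
#'
#' @param table cohort data frame.
#' @param outcomes,predictors column names defining the grid.
#' @param covariates default covariate set.
#' @param reduced_covariates named list mapping predictor name to the
#'   covariate set to use for it instead of the default.
#' @return tidy data frame: one row per outcome x predictor with
#'   standardized beta, p, BH-adjusted p, 95\% CI, VIF and covariate list.
#' @export
regression_grid <- function(table, outcomes, predictors,
                            covariates = c("age", "sex", "education"),
                            reduced_covariates = list()) {
  stopifnot(length(outcomes) >= 1, length(predictors) >= 1)
  rows <- list()
  for (oc in outcomes) {
    fam <- lapply(predictors, function(pr) {
      covs <- if (pr %in% names(reduced_covariates)) {
        reduced_covariates[[pr]]
      } else covariates
      fit <- fit_standardized_lm(table, oc, pr, covs)
      co <- fit$coefficients[fit$coefficients$term == pr, ]
      data.frame(outcome = oc, predictor = pr, beta = co$beta, p = co$p,
                 ci_low = co$ci_low, ci_high = co$ci_high, vif = co$vif,
                 covariates = paste(covs, collapse = "+"),
                 stringsAsFactors = FALSE)
    })
    fam <- do.call(rbind, fam)
    fam$p_adj <- bh_adjust(fam$p)
    rows[[oc]] <- fam
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("outcome", "predictor", "beta", "p", "p_adj",
          "ci_low", "ci_high", "vif", "covariates")]
}

#' Forward-backward stepwise selection with protected covariates
#'
#' Iterates forward entry (add the candidate with the smallest p-value if it
#' is below \code{p_enter}) and backward removal (drop the selected
#' candidate with the largest p-value if it is above \code{p_remove}) until
#' the selected set is stable. Covariates are always retained and never
#' eligible for removal. Deterministic given the table.
#'
#' @param table cohort data frame.
#' @param outcome outcome column.
#' @param candidates candidate predictor columns.
#' @param covariates columns forced into every model.
#' @param p_enter,p_remove entry and removal significance thresholds
#'   (defaults 0.05 and 0.10, the convention of SPSS-style stepwise).
#' @param standardize passed through to the fits.
#' @param max_iter safeguard against cycling; exceeding it is an error
#'   reporting the selection trace.
#' @return list with \code{selected} (possibly empty character vector),
#'   \code{fit} (a \code{std_lm} of covariates + selected; NULL when both
#'   are empty), and \code{trace} of the moves taken.
#' @export
stepwise_select <- function(table, outcome, candidates,
                            covariates = character(),
                            p_enter = 0.05, p_remove = 0.10,
                            standardize = TRUE, max_iter = 100L) {
  stopifnot(length(candidates) >= 1, p_enter <= p_remove)
  check_model_columns(table, c(outcome, candidates, covariates))
  # reject rank-deficient candidate designs up front (e.g. duplicated columns)
  full_design <- as.matrix(as.data.frame(table)[, c(candidates, covariates), drop = FALSE])
  qrd <- qr(scale(full_design))
  if (qrd$rank < ncol(full_design)) {
    dropped <- colnames(full_design)[qrd$pivot[(qrd$rank + 1L):ncol(full_design)]]
    stop(sprintf("rank-deficient design; collinear column(s): %s",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }

  selected <- character()
  trace <- character()
  term_p <- function(preds, term) {
    fit <- fit_standardized_lm(table, outcome, preds, covariates, standardize)
    fit$coefficients$p[fit$coefficients$term == term]
  }
  for (iter in seq_len(max_iter)) {
    changed <- FALSE
    pool <- setdiff(candidates, selected)
    if (length(pool)) {
      entry_p <- vapply(pool, function(cd) term_p(c(selected, cd), cd), numeric(1))
      if (min(entry_p) < p_enter) {
        add <- pool[which.min(entry_p)]
        selected <- c(selected, add)
        trace <- c(trace, sprintf("+%s (p=%.4g)", add, min(entry_p)))
        changed <- TRUE
      }
    }
    if (length(selected)) {
      fit <- fit_standardized_lm(table, outcome, selected, covariates, standardize)
      sel_p <- stats::setNames(
        fit$coefficients$p[match(selected, fit$coefficients$term)], selected)
      if (max(sel_p) > p_remove) {
        drop_term <- names(sel_p)[which.max(sel_p)]
        selected <- setdiff(selected, drop_term)
        trace <- c(trace, sprintf("-%s (p=%.4g)", drop_term, max(sel_p)))
        changed <- TRUE
      }
    }
    if (!changed) {
      fit <- if (length(selected) || length(covariates)) {
        fit_standardized_lm(table, outcome, selected,
                            covariates, standardize)
      } else NULL
      return(list(selected = selected, fit = fit, trace = trace))
    }
  }
  stop(sprintf("stepwise selection did not stabilize in %d iterations; trace: %s",
               max_iter, paste(trace, collapse = " ")), call. = FALSE)
}

#' k-fold cross-validation of the stepwise-selected model
#'
#' Subjects are partitioned into k folds by a seeded shuffle; stepwise
#' selection is re-run inside every training fold and the selected model
#' (plus forced covariates) is fit on the training fold and evaluated on the
#' held-out fold. The out-of-sample MSE is computed on the raw outcome
#' scale. Per-fold selected sets are reported to expose selection
#' stability; the adjusted R-squared comes from a full-data refit of the
#' full-data selection.
#'
#' @param table cohort data frame.
#' @param outcome,candidates,covariates as in \code{\link{stepwise_select}}.
#' @param k number of folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @param p_enter,p_remove stepwise thresholds.
#' @return list: \code{mean_mse}, \code{fold_mse}, \code{fold_selected},
#'   \code{selected} (full-data selection), \code{adj_r_squared} (full-data
#'   refit), \code{fit}, \code{folds} (assignment vector).
#' @export
kfold_cv <- function(table, outcome, candidates, covariates = character(),
                     k = 10L, seed = 1L, p_enter = 0.05, p_remove = 0.10) {
  n <- nrow(table)
  k <- assert_count(k, "k", min = 2L)
  if (k > n) stop("`k` cannot exceed the number of subjects", call. = FALSE)
  folds <- with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  fold_mse <- numeric(k)
  fold_selected <- vector("list", k)
  for (i in seq_len(k)) {
    train <- table[folds != i, , drop = FALSE]
    test <- table[folds == i, , drop = FALSE]
    sel <- stepwise_select(train, outcome, candidates, covariates,
                           p_enter, p_remove)$selected
    rhs <- c(covariates, sel)
    form <- if (length(rhs)) stats::reformulate(rhs, outcome) else
      stats::reformulate("1", outcome)
    fit <- stats::lm(form, data = train)
    pred <- stats::predict(fit, newdata = test)
    fold_mse[i] <- mean((test[[outcome]] - pred)^2)
    fold_selected[[i]] <- sel
  }
  full <- stepwise_select(table, outcome, candidates, covariates,
                          p_enter, p_remove)
  list(mean_mse = mean(fold_mse), fold_mse = fold_mse,
       fold_selected = fold_selected, selected = full$selected,
       adj_r_squared = if (!is.null(full$fit)) full$fit$adj_r_squared else NA_real_,
       fit = full$fit, folds = folds)
}
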