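#' Ordinary-least-squares paths of a simple mediation model
#'
#' Estimates the four paths of the X -> M -> Y system with a common
#' covariate set: a from the regression of M on X, b and c' from the
#' regression of Y on X and M, and the total effect c from the regression
#' of Y on X alone. With identical covariates in all three models the
#' decomposition c = c' + a b holds exactly (up to floating point). By
#' default all variables are z-scored first so the paths are standardized
#' coefficients.
#'
#' @param table cohort data frame.
#' @param x,m,y exposure, mediator and outcome columns.
#' @param covariates columns adjusted for in every path model.
#' @param standardize z-score all variables before fitting (default TRUE);
#'   set FALSE to recover coefficients on the generative scale.
#' @return list with paths \code{a}, \code{b}, \code{c}, \code{c_prime},
#'   their p-values (\code{a_p}, \code{b_p}, \code{c_p}, \code{c_prime_p})
#'   and \code{indirect = a * b}.
#' @export
fit_paths <- function(table, x, m, y,
                      covariates = c("age", "sex", "education"),
                      standardize = TRUE) {
  fit_m <- fit_standardized_lm(table, m, x, covariates, standardize)
  fit_y <- fit_standardized_lm(table, y, c(x, m), covariates, standardize)
  fit_c <- fit_standardized_lm(table, y, x, covariates, standardize)
  pick <- function(fit, term, col) {
    fit$coefficients[[col]][fit$coefficients$term == term]
  }
  a <- pick(fit_m, x, "beta")
  b <- pick(fit_y, m, "beta")
  c_prime <- pick(fit_y, x, "beta")
  c_total <- pick(fit_c, x, "beta")
  list(a = a, b = b, c = c_total, c_prime = c_prime,
       indirect = a * b,
       a_p = pick(fit_m, x, "p"), b_p = pick(fit_y, m, "p"),
       c_p = pick(fit_c, x, "p"), c_prime_p = pick(fit_y, x, "p"))
}

#' Percentile-bootstrap confidence interval for the indirect effect
#'
#' Resamples subjects with replacement, recomputes a b on each resample via
#' the two path regressions, and returns the 2.5/97.5 percentile bounds of
#' the bootstrap distribution (bias-corrected bounds optionally).
#' Standardization is performed once on the full sample before resampling,
#' so path coefficients stay on a common scale across resamples. A resample
#' whose design is degenerate (constant exposure or mediator, e.g. an
#' all-zero draw of a rare binary exposure) is redrawn and the redraw count
#' reported. Deterministic given the seed.
#'
#' @param table cohort data frame.
#' @param x,m,y,covariates as in \code{\link{fit_paths}}.
#' @param n_boot number of bootstrap resamples (default 5000; >= 1000
#'   recommended for reporting).
#' @param seed integer seed.
#' @param ci_type "percentile" (default) or "bias_corrected".
#' @param standardize z-score on the full sample before resampling.
#' @return list with \code{ci_low}, \code{ci_high}, \code{indirect}
#'   (full-sample point estimate), \code{boot} (resampled a b values),
#'   \code{n_redraws}.
#' @export
bootstrap_indirect <- function(table, x, m, y,
                               covariates = c("age", "sex", "education"),
                               n_boot = 5000L, seed = 1L,
                               ci_type = c("percentile", "bias_corrected"),
                               standardize = TRUE) {
  ci_type <- match.arg(ci_type)
  n_boot <- assert_count(n_boot, "n_boot")
  cols <- c(x, m, y, covariates)
  check_model_columns(table, cols)
  df <- as.data.frame(table)[, cols, drop = FALSE]
  if (standardize) df <- zscore_columns(df, cols)
  n <- nrow(df)
  xv <- df[[x]]; mv <- df[[m]]; yv <- df[[y]]
  cv <- as.matrix(df[, covariates, drop = FALSE])
  design_m <- cbind(1, xv, cv)          # M ~ X + covariates
  design_y <- cbind(1, xv, mv, cv)      # Y ~ X + M + covariates

  a_hat <- stats::.lm.fit(design_m, mv)$coefficients[2]
  b_hat <- stats::.lm.fit(design_y, yv)$coefficients[3]
  indirect <- a_hat * b_hat

  boot <- numeric(n_boot)
  n_redraws <- 0L
  with_seed(seed, {
    for (i in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (stats::sd(xv[idx]) > 0 && stats::sd(mv[idx]) > 0) break
        n_redraws <- n_redraws + 1L
      }
      a_i <- stats::.lm.fit(design_m[idx, , drop = FALSE], mv[idx])$coefficients[2]
      b_i <- stats::.lm.fit(design_y[idx, , drop = FALSE], yv[idx])$coefficients[3]
      boot[i] <- a_i * b_i
    }
  })
  if (ci_type == "percentile") {
    ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE)
  } else {
    # bias-corrected: shift percentile points by the median bias z0
    prop_below <- mean(boot < indirect)
    prop_below <- min(max(prop_below, 1 / (n_boot + 1)), n_boot / (n_boot + 1))
    z0 <- stats::qnorm(prop_below)
    probs <- stats::pnorm(2 * z0 + stats::qnorm(c(0.025, 0.975)))
    ci <- stats::quantile(boot, probs, names = FALSE)
  }
  list(ci_low = ci[1], ci_high = ci[2], indirect = indirect,
       boot = boot, n_redraws = n_redraws, ci_type = ci_type)
}

#' Classify a mediation result
#'
#' "full" mediation when the bootstrap CI for the indirect effect excludes
#' zero and the direct effect c' is not significant; "partial" when the CI
#' excludes zero and c' is significant; "none" otherwise.
#'
#' @param ci_low,ci_high bootstrap CI bounds for a b.
#' @param c_prime_p p-value of the direct effect.
#' @param alpha significance level for c' (default 0.05).
#' @export
classify_mediation <- function(ci_low, ci_high, c_prime_p, alpha = 0.05) {
  excludes_zero <- ci_low > 0 || ci_high < 0
  if (!excludes_zero) return("none")
  if (c_prime_p >= alpha) "full" else "partial"
}

#' Simple mediation analysis with bootstrap confidence interval
#'
#' Combines \code{\link{fit_paths}}, \code{\link{bootstrap_indirect}} and
#' \code{\link{classify_mediation}} into one PROCESS-style report.
#'
#' @inheritParams bootstrap_indirect
#' @param alpha significance level for the direct-effect test.
#' @return a \code{mediation_result}: paths, indirect effect with bootstrap
#'   CI, classification, and bookkeeping (n_boot, seed, covariates).
#' @export
mediate <- function(table, x, m, y,
                    covariates = c("age", "sex", "education"),
                    n_boot = 5000L, seed = 1L, alpha = 0.05,
                    ci_type = "percentile", standardize = TRUE) {
  paths <- fit_paths(table, x, m, y, covariates, standardize)
  bt <- bootstrap_indirect(table, x, m, y, covariates, n_boot, seed,
                           ci_type, standardize)
  structure(
    c(paths,
      list(ci_low = bt$ci_low, ci_high = bt$ci_high,
           n_boot = n_boot, seed = seed, n_redraws = bt$n_redraws,
           ci_type = bt$ci_type, covariates = covariates,
           x = x, m = m, y = y, alpha = alpha,
           classification = classify_mediation(bt$ci_low, bt$ci_high,
                                               paths$c_prime_p, alpha))),
    class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  star <- function(p) if (p < x$alpha) "*" else ""
  cat(sprintf("Mediation: %s -> %s -> %s (controlling for %s)\n",
              x$x, x$m, x$y, paste(x$covariates, collapse = ", ")))
  cat(sprintf("  a  = %7.3f%s   (%s -> %s)\n", x$a, star(x$a_p), x$x, x$m))
  cat(sprintf("  b  = %7.3f%s   (%s -> %s)\n", x$b, star(x$b_p), x$m, x$y))
  cat(sprintf("  c  = %7.3f%s   (total effect)\n", x$c, star(x$c_p)))
  cat(sprintf("  c' = %7.3f%s   (direct effect)\n", x$c_prime, star(x$c_prime_p)))
  cat(sprintf("  indirect a*b = %.3f, %s 95%% CI [%.3f, %.3f] (%d resamples)\n",
              x$indirect, x$ci_type, x$ci_low, x$ci_high, x$n_boot))
  cat(sprintf("  classification: %s mediation\n", x$classification))
  invisible(x)
}
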