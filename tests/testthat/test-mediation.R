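test_that("paths are recovered exactly on equation-wise noise-free data", {
  # a noise-free M-equation makes M an exact linear function of X and the
  # covariates, so M cannot appear as a regressor; exactness is therefore
  # checked per equation.
  truth_m <- mediation_truth(a_path = 0.5, b_path = 0.4, c_prime = 0.2,
                             noise_m_sd = 0, noise_y_sd = 1,
                             x_kind = "continuous")
  coh <- simulate_cohort(100, truth_m, seed = 14)
  fit_a <- suppressWarnings(fit_standardized_lm(
    coh, "ri_percent", "mbs_present", c("age", "sex", "education"),
    standardize = FALSE))
  expect_equal(fit_a$coefficients$beta[1], 0.5, tolerance = 1e-10)

  truth_y <- mediation_truth(a_path = 0.5, b_path = 0.4, c_prime = 0.2,
                             noise_m_sd = 1, noise_y_sd = 0,
                             x_kind = "continuous")
  coh <- simulate_cohort(100, truth_y, seed = 15)
  paths <- suppressWarnings(fit_paths(coh, "mbs_present", "ri_percent",
                                      "memory_z", standardize = FALSE))
  expect_equal(paths$b, 0.4, tolerance = 1e-10)
  expect_equal(paths$c_prime, 0.2, tolerance = 1e-10)
  expect_equal(paths$c, paths$c_prime + paths$a * paths$b, tolerance = 1e-10)
})

test_that("effect decomposition c = c' + a*b holds on arbitrary data", {
  for (s in 1:5) {
    coh <- simulate_cohort(80, mediation_truth(x_kind = "continuous"), seed = s)
    for (std in c(TRUE, FALSE)) {
      paths <- fit_paths(coh, "mbs_present", "ri_percent", "memory_z",
                         standardize = std)
      expect_lt(abs(paths$c - (paths$c_prime + paths$a * paths$b)), 1e-10)
    }
  }
})

test_that("an independent mediator yields null a and b and c close to c'", {
  set.seed(15)
  n <- 5000
  tab <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5),
                    education = rnorm(n), x = rnorm(n), m = rnorm(n))
  tab$y <- 0.3 * tab$x + rnorm(n)
  paths <- fit_paths(tab, "x", "m", "y")
  expect_lt(abs(paths$a), 0.05)
  expect_lt(abs(paths$b), 0.05)
  expect_lt(abs(paths$c - paths$c_prime), 0.01)
})

test_that("bootstrap CI is seed-deterministic and brackets the point estimate", {
  coh <- simulate_cohort(150, mediation_truth(x_kind = "continuous"), seed = 16)
  b1 <- bootstrap_indirect(coh, "mbs_present", "ri_percent", "memory_z",
                           n_boot = 400, seed = 99)
  b2 <- bootstrap_indirect(coh, "mbs_present", "ri_percent", "memory_z",
                           n_boot = 400, seed = 99)
  expect_identical(b1$boot, b2$boot)
  expect_identical(c(b1$ci_low, b1$ci_high), c(b2$ci_low, b2$ci_high))
  expect_lte(b1$ci_low, b1$indirect)
  expect_gte(b1$ci_high, b1$indirect)

  b3 <- bootstrap_indirect(coh, "mbs_present", "ri_percent", "memory_z",
                           n_boot = 400, seed = 99, ci_type = "bias_corrected")
  expect_true(is.finite(b3$ci_low) && is.finite(b3$ci_high))
})

test_that("degenerate resamples of a rare binary exposure are redrawn", {
  # prevalence so low that all-zero resamples occur often
  set.seed(17)
  n <- 30
  tab <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5),
                    education = rnorm(n),
                    x = c(1, rep(0, n - 1)))
  tab$m <- 0.5 * tab$x + rnorm(n)
  tab$y <- 0.4 * tab$m + rnorm(n)
  bt <- bootstrap_indirect(tab, "x", "m", "y", n_boot = 300, seed = 18)
  expect_gt(bt$n_redraws, 0)
  expect_true(all(is.finite(bt$boot)))
})

test_that("classification follows the CI / direct-effect rule", {
  expect_equal(classify_mediation(0.05, 0.20, c_prime_p = 0.40), "full")
  expect_equal(classify_mediation(0.05, 0.20, c_prime_p = 0.01), "partial")
  expect_equal(classify_mediation(-0.02, 0.15, c_prime_p = 0.01), "none")
  expect_equal(classify_mediation(-0.20, -0.05, c_prime_p = 0.50), "full")
})

test_that("path estimates are consistent: RMSE shrinks with sample size", {
  truth <- mediation_truth(a_path = 0.5, b_path = 0.4, c_prime = 0.2,
                           x_kind = "continuous")
  rmse_ab <- function(n, n_rep = 20) {
    errs <- vapply(seq_len(n_rep), function(s) {
      coh <- simulate_cohort(n, truth, seed = 2000 + s)
      p <- fit_paths(coh, "mbs_present", "ri_percent", "memory_z",
                     standardize = FALSE)
      p$indirect - 0.2
    }, numeric(1))
    sqrt(mean(errs^2))
  }
  r100 <- rmse_ab(100); r500 <- rmse_ab(500); r2000 <- rmse_ab(2000)
  expect_lt(r500, r100)
  expect_lt(r2000, r500)
})

test_that("mediate() composes paths, bootstrap and classification", {
  coh <- simulate_cohort(400, mediation_truth(a_path = 0.6, b_path = 0.5,
                                              c_prime = 0,
                                              x_kind = "continuous"),
                         seed = 19)
  res <- mediate(coh, "mbs_present", "ri_percent", "memory_z",
                 n_boot = 500, seed = 20)
  expect_s3_class(res, "mediation_result")
  expect_gt(res$ci_low, 0)  # strong indirect effect
  # the reported classification is internally consistent with the CI and
  # the direct-effect p-value
  expect_equal(res$classification,
               classify_mediation(res$ci_low, res$ci_high, res$c_prime_p))
  expect_true(res$classification %in% c("full", "partial"))
  expect_output(print(res), "classification: (full|partial) mediation")
})
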