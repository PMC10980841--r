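test_that("zscore standardizes to mean 0 and sample SD 1", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(1)
  x <- rnorm(50, 10, 5)
  z <- zscore(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(sd(z) - 1), 1e-12)
  expect_equal(zscore(z), z)  # idempotent on standardized input
  expect_error(zscore(rep(2, 10)), "constant")
})

test_that("BH adjustment reproduces the hand-computed step-up example", {
  # step-up: p * m / rank, then cumulative minimum from the largest rank
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.27, 0.6)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= 0))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("standardized simple-regression beta equals the Pearson correlation", {
  set.seed(6)
  tab <- data.frame(y = rnorm(80), x = rnorm(80))
  fit <- fit_standardized_lm(tab, "y", "x")
  expect_equal(fit$coefficients$beta, cor(tab$x, tab$y), tolerance = 1e-12)
  expect_equal(fit$coefficients$vif, 1)
})

test_that("perfect fit and null predictor behave as expected", {
  set.seed(7)
  tab <- data.frame(x = rnorm(60))
  tab$y <- tab$x
  fit <- suppressWarnings(fit_standardized_lm(tab, "y", "x"))
  expect_equal(fit$coefficients$beta, 1, tolerance = 1e-10)
  expect_lt(fit$coefficients$p, 1e-20)

  tab2 <- data.frame(y = rnorm(5000), x = rnorm(5000))
  expect_lt(abs(fit_standardized_lm(tab2, "y", "x")$coefficients$beta), 0.05)
})

test_that("rank-deficient designs are rejected naming the collinear columns", {
  set.seed(8)
  tab <- data.frame(y = rnorm(40), x1 = rnorm(40))
  tab$x2 <- tab$x1
  expect_error(fit_standardized_lm(tab, "y", c("x1", "x2")), "collinear.*x2")
  expect_error(stepwise_select(tab, "y", c("x1", "x2")), "collinear.*x2")
})

test_that("VIF is 1 for orthogonal predictors and reported per predictor", {
  set.seed(9)
  x1 <- rep(c(-1, 1), each = 20)
  x2 <- rep(c(-1, 1), times = 20)  # exactly orthogonal to x1
  tab <- data.frame(y = rnorm(40), x1 = x1, x2 = x2)
  fit <- fit_standardized_lm(tab, "y", c("x1", "x2"))
  expect_equal(fit$coefficients$vif, c(1, 1), tolerance = 1e-10)
})

test_that("regression grid adjusts p-values within each outcome family", {
  set.seed(10)
  n <- 150
  tab <- data.frame(age = rnorm(n, 58, 6), sex = rbinom(n, 1, 0.5),
                    education = rnorm(n, 9, 3),
                    p1 = rnorm(n), p2 = rnorm(n), p3 = rnorm(n))
  tab$out1 <- 0.5 * tab$p1 + rnorm(n)
  tab$out2 <- rnorm(n)
  grid <- regression_grid(tab, c("out1", "out2"), c("p1", "p2", "p3"),
                          covariates = c("age", "sex", "education"),
                          reduced_covariates = list(p3 = c("age", "sex")))
  expect_equal(nrow(grid), 6)
  for (oc in c("out1", "out2")) {
    fam <- grid[grid$outcome == oc, ]
    expect_equal(fam$p_adj, bh_adjust(fam$p))
  }
  expect_equal(grid$covariates[grid$predictor == "p3"], rep("age+sex", 2))
  expect_true(all(grid$p_adj >= grid$p))
})

test_that("stepwise selection keeps a strong true predictor and protected covariates", {
  set.seed(11)
  n <- 500
  tab <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5),
                    true_pred = rnorm(n), n1 = rnorm(n), n2 = rnorm(n))
  tab$ri <- 0.4 * tab$true_pred + 0.2 * tab$age + rnorm(n)
  sel <- stepwise_select(tab, "ri", c("true_pred", "n1", "n2"),
                         covariates = c("age", "sex"))
  expect_true("true_pred" %in% sel$selected)
  expect_true(all(c("age", "sex") %in% sel$fit$coefficients$term))
  # the trace accounts exactly for the final selection
  expect_equal(sum(grepl("^\\+", sel$trace)) - sum(grepl("^-", sel$trace)),
               length(sel$selected))
})

test_that("stepwise selection on pure noise rarely admits anything strong", {
  # with p_enter = 0.05 and 3 candidates, a false entry that then survives
  # removal at p_remove = 0.10 should be the minority outcome
  set.seed(12)
  empty <- 0
  for (i in 1:40) {
    n <- 200
    tab <- data.frame(y = rnorm(n), a = rnorm(n), b = rnorm(n), c = rnorm(n))
    sel <- stepwise_select(tab, "y", c("a", "b", "c"))
    if (length(sel$selected) == 0) empty <- empty + 1
  }
  expect_gt(empty, 20)
})

test_that("k-fold CV is seed-deterministic and near-exact for a noise-free model", {
  set.seed(13)
  n <- 120
  tab <- data.frame(age = rnorm(n), x = rnorm(n))
  tab$y <- 2 * tab$x + 0.5 * tab$age
  cv1 <- suppressWarnings(kfold_cv(tab, "y", "x", covariates = "age", k = 10, seed = 3))
  cv2 <- suppressWarnings(kfold_cv(tab, "y", "x", covariates = "age", k = 10, seed = 3))
  expect_identical(cv1$folds, cv2$folds)
  expect_equal(cv1$mean_mse, cv2$mean_mse)
  expect_lt(cv1$mean_mse, 1e-20)
  expect_equal(cv1$selected, "x")

  # pure-noise outcome with intercept-only models: CV MSE near Var(y)
  tab2 <- data.frame(y = rnorm(2000), x = rnorm(2000))
  cv3 <- kfold_cv(tab2, "y", "x", covariates = character(0), k = 10, seed = 4)
  expect_equal(cv3$mean_mse, var(tab2$y), tolerance = 0.1)
  expect_error(kfold_cv(tab[1:5, ], "y", "x", k = 10, seed = 1), "exceed")
})
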