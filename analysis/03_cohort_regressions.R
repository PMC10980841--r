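#!/usr/bin/env Rscript
# Stage 3: cohort-level regressions.
#
# (a) Association grid: each cognitive domain regressed on RI, each SVD
#     marker and each cognitive-reserve domain separately (standardized
#     betas), with B/H FDR control within each cognitive domain.
# (b) Predicting RI: Model 1 fits each predictor individually (covariates
#     age, sex, mean FD); Model 2 runs forward-backward stepwise selection
#     over all predictors; Model 3 repeats Model 2 with vascular risk
#     factors added as covariates; the selected model is cross-validated
#     with 10 folds.

suppressPackageStartupMessages(library(redconn))

data_dir <- "results/data"
out_dir <- "results/stats"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- read_run_config(file.path(data_dir, "run_config.yaml"))
cohort <- read_cohort(file.path(data_dir, "cohort.csv"))

domains <- c("global_cognition_z", "memory_z", "language_z",
             "processing_speed_z", "executive_z", "attention_z")
predictors <- c("ri_percent", "cri_education", "cri_work", "cri_leisure",
                "cri_total", "lacunes_present", "mbs_present", "dwpvs",
                "bgpvs", "fazekas_peri", "fazekas_deep", "svd_total")

# CRI-education and CRI-total already encode education, so only age and sex
# are used as covariates for them.
grid <- regression_grid(
  cohort, domains, predictors,
  covariates = c("age", "sex", "education"),
  reduced_covariates = list(cri_education = c("age", "sex"),
                            cri_total = c("age", "sex")))
write.csv(grid, file.path(out_dir, "cognition_associations.csv"),
          row.names = FALSE)
sig <- grid[grid$p_adj < 0.05, c("outcome", "predictor", "beta", "p", "p_adj")]
cat(sprintf("association grid: %d tests, %d significant after B/H within domain\n",
            nrow(grid), nrow(sig)))
if (nrow(sig)) print(sig, row.names = FALSE, digits = 3)

# --- predicting RI ----------------------------------------------------------
ri_predictors <- c("cri_education", "cri_work", "cri_leisure", "cri_total",
                   "lacunes_present", "mbs_present", "dwpvs", "bgpvs",
                   "fazekas_peri", "fazekas_deep", "svd_total")
base_covs <- c("age", "sex", "mean_fd")
vasc_covs <- c(base_covs, "smoking", "hypertension", "diabetes",
               "hyperlipidemia", "hyperhomocysteinemia")

model1 <- do.call(rbind, lapply(ri_predictors, function(pr) {
  fit <- fit_standardized_lm(cohort, "ri_percent", pr, base_covs)
  co <- fit$coefficients[fit$coefficients$term == pr, ]
  data.frame(predictor = pr, beta = co$beta, p = co$p,
             ci_low = co$ci_low, ci_high = co$ci_high, vif = co$vif)
}))
write.csv(model1, file.path(out_dir, "ri_model1_individual.csv"),
          row.names = FALSE)
cat("\nModel 1 (individual predictors of RI, adjusted for age/sex/meanFD):\n")
print(model1[model1$p < 0.05, ], row.names = FALSE, digits = 3)

sel2 <- stepwise_select(cohort, "ri_percent", ri_predictors, base_covs,
                        p_enter = cfg$stepwise_p_enter,
                        p_remove = cfg$stepwise_p_remove)
cat(sprintf("\nModel 2 stepwise selection: %s\n",
            paste(sel2$selected, collapse = ", ")))
sel3 <- stepwise_select(cohort, "ri_percent", ri_predictors, vasc_covs,
                        p_enter = cfg$stepwise_p_enter,
                        p_remove = cfg$stepwise_p_remove)
cat(sprintf("Model 3 stepwise selection (vascular covariates added): %s\n",
            paste(sel3$selected, collapse = ", ")))
cat(sprintf("Model 3 adjusted R^2 = %.4f, MSE = %.4f, max VIF = %.2f\n",
            sel3$fit$adj_r_squared, sel3$fit$mse,
            max(sel3$fit$coefficients$vif)))

cv <- kfold_cv(cohort, "ri_percent", ri_predictors, vasc_covs,
               k = cfg$cv_folds, seed = cfg$seed,
               p_enter = cfg$stepwise_p_enter,
               p_remove = cfg$stepwise_p_remove)
cat(sprintf("10-fold CV: mean out-of-fold MSE = %.4f; full-data adj R^2 = %.4f\n",
            cv$mean_mse, cv$adj_r_squared))
sel_tab <- table(unlist(cv$fold_selected))
cat("per-fold selection frequency:\n")
print(sel_tab)

model23 <- rbind(
  cbind(model = "model2", sel2$fit$coefficients),
  cbind(model = "model3", sel3$fit$coefficients))
write.csv(model23, file.path(out_dir, "ri_model23_stepwise.csv"),
          row.names = FALSE)
write.csv(data.frame(fold = seq_along(cv$fold_mse), mse = cv$fold_mse,
                     selected = vapply(cv$fold_selected, paste,
                                       character(1), collapse = "+")),
          file.path(out_dir, "ri_model3_cv.csv"), row.names = FALSE)
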