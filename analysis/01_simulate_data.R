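#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# No participant data are distributed with this project, so the whole
# analysis runs on synthetic inputs with known ground truth: (i) per-subject
# parcellated BOLD series drawn from a block-covariance model, and (ii) a
# cohort table whose exposure -> redundancy-index -> memory system follows
# known path coefficients.

suppressPackageStartupMessages(library(redconn))

data_dir <- "results/data"
ts_dir <- "scratch/ts"   # bulky per-subject intermediates, regenerable
dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)
dir.create(ts_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- default_run_config()
write_run_config(cfg, file.path(data_dir, "run_config.yaml"))

# --- parcellated time series ------------------------------------------------
# 10 subjects, 100 regions in two communities, 240 volumes at TR = 2 s
# (an 8-minute scan). Community contrast and unit noise give windows on
# both sides of the connected/two-connected transition.
n_subjects_ts <- 10L
model <- cov_model(100, block_sizes = c(50, 50), within_block_corr = 0.35,
                   between_block_corr = 0.12, noise_sd = 1)
for (s in seq_len(n_subjects_ts)) {
  ts <- simulate_timeseries(model, 240, seed = cfg$seed * 1000 + s,
                            tr_seconds = cfg$tr_seconds)
  write_timeseries(ts, file.path(ts_dir, sprintf("S%04d.tsv", s)))
}
cat(sprintf("wrote %d parcellated series (240 volumes x 100 regions) to %s\n",
            n_subjects_ts, ts_dir))

# --- cohort table -----------------------------------------------------------
# 121 subjects (the cohort size the covariate distributions emulate), binary
# exposure at ~10% prevalence, and a mediation system with a = 0.5, b = 0.4,
# c' = 0.2 on the generative scale.
truth <- mediation_truth(a_path = 0.5, b_path = 0.4, c_prime = 0.2,
                         noise_m_sd = 1, noise_y_sd = 1, x_kind = "binary")
cohort <- simulate_cohort(121, truth, seed = cfg$seed)
write_cohort(cohort, file.path(data_dir, "cohort.csv"))
cat(sprintf("wrote cohort table: %d subjects, %d columns (exposure prevalence %.1f%%)\n",
            nrow(cohort), ncol(cohort), 100 * mean(cohort$mbs_present)))
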