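#!/usr/bin/env Rscript
# Calibration and power of the full pipeline on repeated synthetic cohorts:
#  - type-I error of the carbonyl-ratio omnibus test on null cohorts
#  - frequency of clean PC-side separation and of a significant carbonyl
#    omnibus on coriell-like cohorts
# This driver uses reduced repetition counts for a quick desk run; the full
# 5000/100-rep versions are exercised by the test suite and
# scripts/acceptance.R.

suppressPackageStartupMessages(library(ftirfp))

out <- "results"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed0 <- 77000L

n_null <- 500
cfg_null <- default_profiles("null", n_samples_per_group = 3)
rej <- 0
for (r in seq_len(n_null)) {
  sim <- simulate_cohort(cfg_null, seed = seed0 + r, ground_truth = FALSE)
  est <- compute_ratios(preprocess_pipeline(sim$set))
  p <- kruskal_wallis(split(est$carbonyl_total_lipid, est$group))$p_value
  rej <- rej + (p <= 0.05)
}
cat(sprintf("null cohorts: omnibus rejection %d/%d = %.3f (nominal 0.05)\n",
            rej, n_null, rej / n_null))

n_coh <- 25
sep <- 0; sig <- 0
for (r in seq_len(n_coh)) {
  rep_r <- run_pipeline(list(seed = seed0 + r,
                             input = list(scenario = "coriell")))
  reg <- rep_r$regions[["2800-3000"]]
  ok <- FALSE
  for (j in intersect(1:3, seq_along(reg$side_tables))) {
    tb <- reg$side_tables[[j]]
    if (all(tb$fraction_positive %in% c(0, 1)) &&
        tb$side[tb$group == "DM1_2000"] != tb$side[tb$group == "control"] &&
        tb$side[tb$group == "DM1_2000"] != tb$side[tb$group == "DM1_1000"]) {
      ok <- TRUE
    }
  }
  sep <- sep + ok
  kw <- subset(rep_r$stats,
               ratio == "carbonyl_total_lipid" & test == "kruskal_wallis")
  sig <- sig + (nrow(kw) == 1 && kw$p_value <= 0.05)
}
cat(sprintf("coriell cohorts: clean DM1_2000 separation %d/%d, significant carbonyl omnibus %d/%d\n",
            sep, n_coh, sig, n_coh))

tab <- data.frame(
  quantity = c("null_omnibus_rejection_rate", "coriell_separation_fraction",
               "coriell_carbonyl_omnibus_significant_fraction"),
  value = c(rej / n_null, sep / n_coh, sig / n_coh),
  n = c(n_null, n_coh, n_coh))
write.csv(tab, file.path(out, "calibration.csv"), row.names = FALSE)
cat("calibration summary written to results/calibration.csv\n")
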