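#!/usr/bin/env Rscript
# Lipid intensity ratios (CH2/CH3, carbonyl/total lipid, unsaturated/
# saturated) from the full-range second derivatives, followed by the
# nonparametric battery: normality screen, Kruskal-Wallis omnibus, Dunn-type
# many-to-one post hoc vs control, pairwise Mann-Whitney U.

suppressPackageStartupMessages(library(ftirfp))

out <- "results/ratios"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

for (scenario in c("coriell", "neurolab")) {
  deriv <- read_spectra_csv(
    sprintf("results/preprocessed/%s_second_derivative.csv", scenario),
    sprintf("results/preprocessed/%s_metadata.csv", scenario))
  ratios <- compute_ratios(deriv)
  write.csv(ratios, file.path(out, sprintf("%s_ratios.csv", scenario)),
            row.names = FALSE)
  stats_tab <- ratio_stats(ratios, control = "control")
  write.csv(stats_tab, file.path(out, sprintf("%s_stats.csv", scenario)),
            row.names = FALSE)

  cat(sprintf("\n== %s cohort ==\n", scenario))
  for (rc in c("ch2_ch3", "carbonyl_total_lipid", "unsat_sat")) {
    med <- tapply(ratios[[rc]], ratios$group, median, na.rm = TRUE)
    kw <- stats_tab[stats_tab$ratio == rc & stats_tab$test == "kruskal_wallis", ]
    cat(sprintf("%-22s medians: %s | omnibus H = %.3f, p = %.4g%s\n", rc,
                paste(sprintf("%s %.3f", names(med), med), collapse = ", "),
                kw$statistic, kw$p_value,
                if (kw$significant) " *" else ""))
    ph <- stats_tab[stats_tab$ratio == rc & stats_tab$test == "manytoone_rank" &
                      stats_tab$significant, ]
    if (nrow(ph) > 0) {
      cat(sprintf("  significant vs control (adjusted): %s\n",
                  paste(ph$comparison, collapse = "; ")))
    }
  }
}
cat("\nratio and stats tables written to", out, "\n")
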