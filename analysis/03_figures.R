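#!/usr/bin/env Rscript
# Step 3 — figures (requires ggplot2).
#
# Two figures from the calibrated model and the scenario simulation:
#   results/figures/typical_profiles.pdf  steady-state concentration-time
#     profiles of the typical 70 kg patient under each scenario, one week at
#     steady state, with the 0.0568 mg/L efficacy trough threshold;
#   results/figures/metric_boxplots.pdf   per-patient trough and average
#     concentration distributions by scenario.
#
# Run steps 1 and 2 first (the script re-runs them if outputs are missing).
# Run from the repository root: Rscript analysis/03_figures.R

suppressPackageStartupMessages(library(lazdose))
if (!requireNamespace("ggplot2", quietly = TRUE))
  stop("ggplot2 is required for this step")

dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)

model_path <- "results/calibrated_model.json"
if (!file.exists(model_path)) {
  cat("No saved model; running calibration first\n")
  write_model_json(calibrate_model(seed = 2025), model_path)
}
typ <- read_model_json(model_path)

p1 <- plot_typical_profiles(typ) +
  ggplot2::geom_hline(yintercept = 0.0568, linetype = "dashed") +
  ggplot2::annotate("text", x = 0, y = 0.0568, vjust = -0.5, hjust = 0,
                    size = 3, label = "efficacy trough threshold")
ggplot2::ggsave("results/figures/typical_profiles.pdf", p1,
                width = 7, height = 4)

report <- run_paper_scenarios(typ, n = 10000, seed = 2025,
                              keep_patients = TRUE)
p2 <- plot_metric_boxplots(report)
ggplot2::ggsave("results/figures/metric_boxplots.pdf", p2,
                width = 7, height = 4)

cat("Wrote results/figures/typical_profiles.pdf and",
    "results/figures/metric_boxplots.pdf\n")
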