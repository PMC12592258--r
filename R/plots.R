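# Figure helpers (ggplot2 is optional; these mirror the typical-individual
# profile overlays and the per-scenario metric boxplots).

#' Typical-individual steady-state profiles for a set of scenarios
#'
#' @param typical A [typical_model()].
#' @param scenarios Named list of `list(genotype = , regimen = )` entries;
#'   defaults to the published scenario set.
#' @param window,grid_step Passed to [css_profile()].
#' @return A ggplot object.
#' @export
plot_typical_profiles <- function(typical, scenarios = NULL, window = 168,
                                  grid_step = 0.1) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  if (inherits(typical, "calibration_result")) typical <- typical$typical
  if (is.null(scenarios))
    scenarios <- list(
      "non-null 240 mg QD" = list(genotype = "non-null", regimen = regimen_preset("240QD")),
      "null 240 mg QD" = list(genotype = "null", regimen = regimen_preset("240QD")),
      "null 160 mg QD" = list(genotype = "null", regimen = regimen_preset("160QD")),
      "null 240 mg QOD" = list(genotype = "null", regimen = regimen_preset("240QOD")))
  df <- do.call(rbind, lapply(names(scenarios), function(k) {
    s <- scenarios[[k]]
    p <- individualize(typical, typical$ref_weight, s$genotype)
    prof <- css_profile(p, s$regimen, window, grid_step)
    cbind(scenario = k, as.data.frame(prof))
  }))
  ggplot2::ggplot(df, ggplot2::aes(time_h, conc_mg_per_L,
                                   colour = scenario)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time at steady state (h)",
                  y = "Lazertinib concentration (mg/L)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Boxplots of per-patient exposure metrics by scenario
#'
#' @param report A `dosing_report` built with `keep_patients = TRUE`.
#' @return A ggplot object.
#' @export
plot_metric_boxplots <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  df <- report_long_metrics(report)
  ggplot2::ggplot(df, ggplot2::aes(scenario, value)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Concentration (mg/L)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
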