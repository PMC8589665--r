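# Diagnostic figures: per-patient reaction-time densities with mixture
# overlays, and meta-analysis scatter plots.

#' Plot a reaction-time histogram with mixture overlays
#'
#' Histogram of (normalized) reaction times with the fitted 1-component
#' and 2-component Gaussian mixture densities superimposed, the standard
#' visual check on a bimodality verdict.
#'
#' @param x Numeric vector of reaction times (ms).
#' @param fit1,fit2 `"mixture_fit"` objects for the same data (e.g. from
#'   [analyze_bimodality()]).
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_rt_mixture <- function(x, fit1, fit2, bins = 15) {
  grid <- seq(min(x) - stats::sd(x), max(x) + stats::sd(x), length.out = 400)
  dens <- function(fit) {
    rowSums(vapply(seq_along(fit$weights), function(j) {
      fit$weights[j] * stats::dnorm(grid, fit$means[j], sqrt(fit$variances[j]))
    }, numeric(length(grid))))
  }
  curves <- rbind(data.frame(rt = grid, density = dens(fit1), model = "unimodal"),
                  data.frame(rt = grid, density = dens(fit2), model = "bimodal"))
  ggplot2::ggplot(data.frame(rt = x), ggplot2::aes(x = rt)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80", colour = "grey50") +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(y = density, colour = model),
                       linewidth = 0.9) +
    ggplot2::scale_colour_manual(values = c(unimodal = "#3366BB",
                                            bimodal = "#CC3333")) +
    ggplot2::labs(x = "reaction time (ms)", y = "density", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter plot of a meta-analysis result
#'
#' Population symptom imbalance against the harmonized outcome, one point
#' per participant population, with the least-squares line.
#'
#' @param meta A `"meta_result"` from [run_meta()].
#' @return A ggplot object.
#' @export
plot_meta_scatter <- function(meta) {
  ylab <- if (meta$outcome_kind == "tab_ms") {
    "traditional attentional bias (ms)"
  } else {
    paste(sub("_", " ", meta$outcome_kind), "BOLD (z)")
  }
  ggplot2::ggplot(meta$data, ggplot2::aes(x = imbalance,
                                          y = outcome)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey40") +
    ggplot2::geom_point(size = 2.5, colour = "#CC3333") +
    ggplot2::labs(x = "symptom imbalance (avoidance - re-experiencing)",
                  y = ylab,
                  subtitle = sprintf("r = %.2f, one-tailed p = %.3f (n = %d populations)",
                                     meta$correlation$r,
                                     meta$correlation$p_one_tailed,
                                     meta$n_populations)) +
    ggplot2::theme_minimal()
}
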