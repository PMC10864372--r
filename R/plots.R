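## ggplot2 views of sweeps, scans and the experiment comparison.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a field sweep
#'
#' Weighted and per-isotopologue singlet-yield curves against field
#' strength (log axis); the low-field dip and any 25Mg spikes are visible
#' directly.
#'
#' @param object An [field_sweep()] result.
#' @param components Include the per-isotopologue curves.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rp_field_sweep <- function(object, components = TRUE, ...) {
  df <- tidy(object)
  if (!components) df <- df |> dplyr::filter(.data$component == "weighted")
  kin <- attr(object, "kinetics")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$b, y = 100 * .data$phi_s,
    colour = .data$component
  )) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "magnetic field strength B (mT)",
      y = expression(Phi[S] ~ "(%)"),
      colour = NULL,
      title = sprintf(
        "%s pathway, k = %.2g, r = %.2g s⁻¹",
        attr(object, "params")$label, kin$k, kin$r
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a k-r scan
#'
#' Heatmap of the yield ratio `S` over the log-log rate plane, with an
#' optional contour marking a ratio threshold.
#'
#' @param object An [kr_scan()] result.
#' @param threshold Contour level to outline (NULL for none).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rp_kr_scan <- function(object, threshold = 1.2, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$k, y = .data$r, fill = .data$s
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c(option = "viridis") +
    ggplot2::labs(
      x = expression(k ~ (s^-1)), y = expression(r ~ (s^-1)),
      fill = "S",
      title = sprintf(
        "%s pathway: S = Φ(%g mT) / Φ(%g mT)",
        attr(object, "params")$label,
        attr(object, "b_exp"), attr(object, "b_0")
      )
    ) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_contour(
      ggplot2::aes(z = .data$s),
      breaks = threshold, colour = "black", linewidth = 0.3
    )
  }
  p
}

#' Plot a model-vs-experiment comparison
#'
#' Experimental field/control uptake ratios per NMDA concentration with the
#' model yield ratio overlaid as a horizontal line.
#'
#' @param object An [compare_model_to_experiment()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rp_ca_comparison <- function(object, ...) {
  ggplot2::ggplot(
    object$ratios,
    ggplot2::aes(x = factor(.data$nmda_um), y = .data$ratio)
  ) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_hline(
      yintercept = object$s,
      colour = "firebrick", linetype = 2
    ) +
    ggplot2::labs(
      x = expression(NMDA ~ (mu * M)),
      y = "field / control uptake ratio",
      title = sprintf(
        "model S = %.2f vs %s-exposure ratios (%s)",
        object$s, object$exposure, object$note
      )
    ) +
    ggplot2::theme_minimal()
}
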