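# ggplot2 methods for screen results and assay traces.

#' @method autoplot primary_screen
#' @export
autoplot.primary_screen <- function(object, ...) {
  df <- tidy(object)
  df$direction <- ifelse(is.na(df$direction), "not significant", df$direction)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r,
                                   y = -log10(.data$p_value),
                                   colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::geom_hline(yintercept = -log10(object$alpha), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(
      resistance_associated = "#b2182b",
      sensitivity_associated = "#2166ac",
      `not significant` = "grey65")) +
    ggplot2::labs(x = "Pearson r (expression vs log10 GI50)",
                  y = expression(-log[10]~italic(P)),
                  colour = NULL,
                  title = "Panel gene-drug correlation screen") +
    ggplot2::theme_minimal()
}

#' @method autoplot paired_screen
#' @export
autoplot.paired_screen <- function(object, ...) {
  pairs <- unique(object$per_pair$pair)
  if (length(pairs) < 2) {
    df <- dplyr::left_join(object$per_pair, object$records, by = "probe_id")
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_fc,
                                       y = -log10(.data$p),
                                       colour = .data$direction)) +
        ggplot2::geom_point(alpha = 0.5, size = 0.8) +
        ggplot2::labs(x = "log2 fold change (sensitive - resistant)",
                      y = expression(-log[10]~italic(P))) +
        ggplot2::theme_minimal()
    )
  }
  wide <- tidyr::pivot_wider(object$per_pair, id_cols = "probe_id",
                             names_from = "pair", values_from = "log2_fc")
  wide <- dplyr::left_join(wide, object$records, by = "probe_id")
  ggplot2::ggplot(wide, ggplot2::aes(x = .data[[pairs[1]]],
                                     y = .data[[pairs[2]]],
                                     colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::scale_colour_manual(values = c(
      higher_in_sensitive = "#2166ac",
      higher_in_resistant = "#b2182b",
      none = "grey65")) +
    ggplot2::labs(x = paste("log2 FC,", pairs[1]),
                  y = paste("log2 FC,", pairs[2]),
                  colour = NULL,
                  title = "Paired differential screen: fold-change congruence") +
    ggplot2::theme_minimal()
}

#' @method autoplot integrated_signature
#' @export
autoplot.integrated_signature <- function(object, ...) {
  counts <- dplyr::bind_rows(
    tibble(screen = "panel", direction = "sensitivity",
           n = length(object$provenance$panel_sensitivity)),
    tibble(screen = "panel", direction = "resistance",
           n = length(object$provenance$panel_resistance)),
    tibble(screen = "paired", direction = "sensitivity",
           n = length(object$provenance$paired_sensitivity)),
    tibble(screen = "paired", direction = "resistance",
           n = length(object$provenance$paired_resistance)),
    tibble(screen = "overlap", direction = "sensitivity",
           n = length(object$sensitivity_overlap)),
    tibble(screen = "overlap", direction = "resistance",
           n = length(object$resistance_overlap))
  )
  counts$screen <- factor(counts$screen, levels = c("panel", "paired", "overlap"))
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$screen, y = .data$n,
                                       fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "genes", fill = NULL,
                  title = "Signature sizes per screen and their overlap") +
    ggplot2::theme_minimal()
}

#' Plot a kinetic trace with its fitted linear rate
#'
#' @param trace Data frame with `minute` and `signal` columns.
#' @return A ggplot object; the subtitle reports the fitted slope.
#' @export
plot_kinetic_trace <- function(trace) {
  rate <- kinetic_rate(trace)
  ggplot2::ggplot(as.data.frame(trace),
                  ggplot2::aes(x = .data$minute, y = .data$signal)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "#b2182b", linewidth = 0.6) +
    ggplot2::labs(x = "minute", y = "fluorescence (AU)",
                  title = "NADPH kinetic trace",
                  subtitle = sprintf("fitted rate = %.4g AU/min", rate)) +
    ggplot2::theme_minimal()
}
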