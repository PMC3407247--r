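# broom-style tidy()/glance() methods so screen results drop straight into
# dplyr/ggplot2 workflows.

#' @method tidy primary_screen
#' @export
tidy.primary_screen <- function(x, ...) {
  sig <- dplyr::bind_rows(x$resistance, x$sensitivity)
  dplyr::left_join(x$records,
                   dplyr::select(sig, "probe_id", "rank", "direction"),
                   by = "probe_id")
}

#' @method glance primary_screen
#' @export
glance.primary_screen <- function(x, ...) {
  tibble(n_probes = nrow(x$records),
         n_samples = x$n_samples,
         alpha = x$alpha,
         n_resistance = nrow(x$resistance),
         n_sensitivity = nrow(x$sensitivity),
         n_skipped = nrow(x$skipped))
}

#' @method tidy paired_screen
#' @export
tidy.paired_screen <- function(x, ...) {
  x$per_pair |>
    dplyr::left_join(x$records, by = "probe_id") |>
    dplyr::relocate("gene_symbol", .after = "probe_id")
}

#' @method glance paired_screen
#' @export
glance.paired_screen <- function(x, ...) {
  tibble(n_probes = nrow(x$records),
         n_pairs = length(unique(x$per_pair$pair)),
         residual_df = x$residual_df,
         prior_df = x$params$prior_df,
         prior_var = x$params$prior_var)
}

#' @method tidy gene_signature
#' @export
tidy.gene_signature <- function(x, ...) {
  tibble(gene = x$genes, screen = x$screen, direction = x$direction)
}

#' @method tidy integrated_signature
#' @export
tidy.integrated_signature <- function(x, ...) {
  dplyr::bind_rows(
    tibble(gene = x$sensitivity_overlap, direction = "sensitivity_associated"),
    tibble(gene = x$resistance_overlap, direction = "resistance_associated")
  ) |>
    dplyr::mutate(source_screens = "primary_panel+paired_lines")
}

#' @method glance integrated_signature
#' @export
glance.integrated_signature <- function(x, ...) {
  tibble(n_sensitivity = length(x$sensitivity_overlap),
         n_resistance = length(x$resistance_overlap),
         n_panel_sensitivity = length(x$provenance$panel_sensitivity),
         n_panel_resistance = length(x$provenance$panel_resistance),
         n_paired_sensitivity = length(x$provenance$paired_sensitivity),
         n_paired_resistance = length(x$provenance$paired_resistance))
}
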