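# Tier-3: directional intersection of the panel screen's and the paired
# screen's gene sets into the final integrated signature. Matching is by
# gene symbol, case-insensitively and after whitespace stripping, because
# symbols are the only key the two array platforms share.

#' Directional gene signature
#'
#' An ordered, deduplicated set of gene symbols produced by one screen in
#' one direction. Symbols are normalized at construction (whitespace
#' stripped, upper-cased) so that signatures from different platforms
#' intersect on a common key.
#'
#' @param genes Character vector of gene symbols.
#' @param screen `"primary_panel"` or `"paired_lines"`.
#' @param direction `"sensitivity_associated"` or `"resistance_associated"`.
#' @return An object of class `gene_signature`.
#' @export
gene_signature <- function(genes,
                           screen = c("primary_panel", "paired_lines"),
                           direction = c("sensitivity_associated",
                                         "resistance_associated")) {
  screen <- match.arg(screen)
  direction <- match.arg(direction)
  genes <- toupper(trimws(as.character(genes)))
  genes <- genes[genes != ""]
  genes <- genes[!duplicated(genes)]
  structure(list(genes = genes, screen = screen, direction = direction),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> %s / %s: %d gene(s)\n",
              x$screen, x$direction, length(x$genes)))
  if (length(x$genes) > 0) {
    cat(" ", paste(head(x$genes, 10), collapse = ", "),
        if (length(x$genes) > 10) "..." else "", "\n")
  }
  invisible(x)
}

#' @export
length.gene_signature <- function(x) length(x$genes)

#' Intersect the two screens' directional gene signatures
#'
#' Takes the four signatures (panel and paired, each split into
#' sensitivity- and resistance-associated genes) and intersects them per
#' direction. No re-weighting is applied: the integrated signature is the
#' pure set overlap, with the provenance signatures retained.
#'
#' @param panel_sensitivity,panel_resistance [gene_signature]s from the
#'   panel correlation screen ([collapse_unique_transcripts()]).
#' @param paired_sensitivity,paired_resistance [gene_signature]s from the
#'   paired screen ([congruence_filter()]).
#' @return An object of class `integrated_signature` with character vectors
#'   `sensitivity_overlap` and `resistance_overlap` and the four input
#'   signatures under `provenance`.
#' @export
intersect_signatures <- function(panel_sensitivity, panel_resistance,
                                 paired_sensitivity, paired_resistance) {
  sigs <- list(panel_sensitivity = panel_sensitivity,
               panel_resistance = panel_resistance,
               paired_sensitivity = paired_sensitivity,
               paired_resistance = paired_resistance)
  ok <- vapply(sigs, inherits, logical(1), what = "gene_signature")
  if (!all(ok)) stop_contract("all four inputs must be gene_signature objects")
  expected <- c(panel_sensitivity = "sensitivity_associated",
                panel_resistance = "resistance_associated",
                paired_sensitivity = "sensitivity_associated",
                paired_resistance = "resistance_associated")
  actual <- vapply(sigs, function(s) s$direction, character(1))
  if (!identical(unname(actual), unname(expected))) {
    bad <- names(expected)[actual != expected]
    stop_contract(sprintf("direction label mismatch for: %s",
                          paste(bad, collapse = ", ")))
  }
  sens <- intersect(panel_sensitivity$genes, paired_sensitivity$genes)
  res <- intersect(panel_resistance$genes, paired_resistance$genes)
  both <- intersect(sens, res)
  if (length(both) > 0) {
    stop_contract(sprintf(
      "gene(s) in both directional overlaps (inconsistent inputs): %s",
      paste(both, collapse = ", ")))
  }
  structure(list(sensitivity_overlap = sens, resistance_overlap = res,
                 provenance = sigs),
            class = "integrated_signature")
}

#' @export
print.integrated_signature <- function(x, ...) {
  cat(sprintf("<integrated_signature> %d sensitivity-associated + %d resistance-associated gene(s)\n",
              length(x$sensitivity_overlap), length(x$resistance_overlap)))
  if (length(x$sensitivity_overlap) > 0) {
    cat("  sensitivity:", paste(x$sensitivity_overlap, collapse = ", "), "\n")
  }
  if (length(x$resistance_overlap) > 0) {
    cat("  resistance: ", paste(x$resistance_overlap, collapse = ", "), "\n")
  }
  invisible(x)
}
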