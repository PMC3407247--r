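#' Probe-by-sample expression matrix
#'
#' Container for microarray-style expression data: a numeric matrix with
#' probes as rows and samples as columns, an optional grid of per-entry
#' detection P values (the "A/P call" statistic indicating signal above
#' background), and a scale flag distinguishing raw fluorescence intensities
#' from log2 values. Missing measurements are stored as `NA`, never as zero;
#' downstream statistics use pairwise-complete observations.
#'
#' @param values Numeric matrix; `rownames` are probe identifiers, `colnames`
#'   are sample identifiers. Non-missing entries must be finite.
#' @param detection_p Optional numeric matrix of detection P values in
#'   `[0, 1]` with the same dimensions and dimnames as `values`.
#' @param scale Either `"log2"` (default) or `"raw"`.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `detection_p` and `scale`.
#' @examples
#' m <- matrix(rnorm(6), 2, 3,
#'             dimnames = list(c("p1", "p2"), c("s1", "s2", "s3")))
#' expr_matrix(m)
#' @export
expr_matrix <- function(values, detection_p = NULL, scale = c("log2", "raw")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_format("`values` must be a numeric matrix")
  }
  pid <- rownames(values)
  sid <- colnames(values)
  if (is.null(pid) || is.null(sid)) {
    stop_format("`values` must carry probe rownames and sample colnames")
  }
  dup_p <- unique(pid[duplicated(pid)])
  if (length(dup_p) > 0) {
    stop_format(sprintf("duplicate probe identifier(s): %s",
                        paste(head(dup_p, 5), collapse = ", ")))
  }
  dup_s <- unique(sid[duplicated(sid)])
  if (length(dup_s) > 0) {
    stop_format(sprintf("duplicate sample identifier(s): %s",
                        paste(head(dup_s, 5), collapse = ", ")))
  }
  if (any(is.infinite(values))) {
    stop_value("expression values must be finite (missing cells are NA)")
  }
  if (!is.null(detection_p)) {
    if (!is.matrix(detection_p) || !identical(dim(detection_p), dim(values))) {
      stop_format("`detection_p` must be a matrix with the same dimensions as `values`")
    }
    if (any(detection_p < 0 | detection_p > 1, na.rm = TRUE)) {
      stop_value("detection P values must lie in [0, 1]")
    }
    dimnames(detection_p) <- dimnames(values)
  }
  structure(list(values = values, detection_p = detection_p, scale = scale),
            class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Probe and sample identifiers of an expression matrix
#' @param x An [expr_matrix].
#' @return Character vector of identifiers.
#' @export
probe_ids <- function(x) rownames(x$values)

#' @rdname probe_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d probes x %d samples (%s scale)%s\n",
              nrow(x$values), ncol(x$values), x$scale,
              if (is.null(x$detection_p)) "" else ", with detection P"))
  invisible(x)
}

#' @method as_tibble expr_matrix
#' @export
as_tibble.expr_matrix <- function(x, ...) {
  out <- as_tibble(x$values, rownames = "probe_id")
  out <- tidyr::pivot_longer(out, -"probe_id",
                             names_to = "sample_id", values_to = "value")
  if (!is.null(x$detection_p)) {
    dp <- as_tibble(x$detection_p, rownames = "probe_id")
    dp <- tidyr::pivot_longer(dp, -"probe_id",
                              names_to = "sample_id", values_to = "detection_p")
    out <- dplyr::left_join(out, dp, by = c("probe_id", "sample_id"))
  }
  out
}

# subset an expr_matrix by probe and/or sample identifiers, keeping the
# detection grid aligned
subset_expr <- function(x, probes = NULL, samples = NULL) {
  if (is.null(probes)) probes <- probe_ids(x)
  if (is.null(samples)) samples <- sample_ids(x)
  v <- x$values[probes, samples, drop = FALSE]
  d <- if (is.null(x$detection_p)) NULL else x$detection_p[probes, samples, drop = FALSE]
  expr_matrix(v, detection_p = d, scale = x$scale)
}

#' Per-sample drug response profile
#'
#' Holds the 50%-growth-inhibition concentration (GI50, molar) measured for
#' each cell line in a screening panel and its base-10 logarithm, the
#' phenotype the tier-1 correlation screen regresses expression against.
#'
#' @param sample_id Character vector of unique sample (cell line) identifiers.
#' @param gi50_molar Positive numeric vector of GI50 concentrations in molar
#'   units, one per sample.
#'
#' @return A tibble of class `drug_response` with columns `sample_id`,
#'   `gi50_molar` and `log10_gi50`.
#' @examples
#' drug_response(c("A", "B"), c(1e-6, 3e-5))
#' @export
drug_response <- function(sample_id, gi50_molar) {
  sample_id <- as.character(sample_id)
  if (length(sample_id) != length(gi50_molar)) {
    stop_format("`sample_id` and `gi50_molar` must have the same length")
  }
  dup <- unique(sample_id[duplicated(sample_id)])
  if (length(dup) > 0) {
    stop_format(sprintf("repeated sample identifier(s): %s",
                        paste(head(dup, 5), collapse = ", ")))
  }
  if (any(!is.finite(gi50_molar)) || any(gi50_molar <= 0)) {
    stop_value("GI50 concentrations must be finite and > 0 (molar)")
  }
  out <- tibble(sample_id = sample_id,
                gi50_molar = as.numeric(gi50_molar),
                log10_gi50 = log10(gi50_molar))
  class(out) <- c("drug_response", class(out))
  out
}

#' Probe-to-gene annotation map
#'
#' Validates a many-probes-to-one-gene annotation table. Every probe must map
#' to exactly one nonempty gene symbol; a gene may be represented by several
#' probes (the usual situation on oligonucleotide arrays).
#'
#' @param probe_id Character vector of unique probe identifiers.
#' @param gene_symbol Character vector of nonempty gene symbols, one per probe.
#' @return A tibble with columns `probe_id` and `gene_symbol`.
#' @export
probe_gene_map <- function(probe_id, gene_symbol) {
  probe_id <- as.character(probe_id)
  gene_symbol <- as.character(gene_symbol)
  if (length(probe_id) != length(gene_symbol)) {
    stop_format("`probe_id` and `gene_symbol` must have the same length")
  }
  dup <- unique(probe_id[duplicated(probe_id)])
  if (length(dup) > 0) {
    stop_format(sprintf("probe(s) mapped more than once: %s",
                        paste(head(dup, 5), collapse = ", ")))
  }
  if (any(is.na(gene_symbol) | trimws(gene_symbol) == "")) {
    stop_value("gene symbols must be nonempty")
  }
  tibble(probe_id = probe_id, gene_symbol = gene_symbol)
}

#' Paired sensitive/resistant experimental design
#'
#' Describes one or more pairs of cell-line groups with opposite drug
#' sensitivity (e.g. a sensitive and a resistant myeloma line, and a
#' sensitive and a resistant mantle cell lymphoma line). Each pair names the
#' replicate samples of its sensitive and resistant groups; the groups within
#' a pair must be nonempty and disjoint.
#'
#' @param ... Pair descriptions created with [design_pair()].
#' @return An object of class `paired_design`: a named list of pairs.
#' @examples
#' paired_design(
#'   design_pair("MM",  sensitive = c("MM1S_1", "MM1S_2"),
#'                      resistant = c("U266_1", "U266_2")),
#'   design_pair("MCL", sensitive = c("JeKo_1", "JeKo_2"),
#'                      resistant = c("Granta_1", "Granta_2"))
#' )
#' @export
paired_design <- function(...) {
  pairs <- list(...)
  if (length(pairs) == 1 && is.list(pairs[[1]]) && is.null(pairs[[1]]$pair_name)) {
    pairs <- pairs[[1]]  # allow a pre-built list of design_pair()s
  }
  if (length(pairs) < 1) stop_design("a paired design needs at least one pair")
  ok <- vapply(pairs, function(p) inherits(p, "design_pair"), logical(1))
  if (!all(ok)) stop_design("every pair must be built with design_pair()")
  nm <- vapply(pairs, function(p) p$pair_name, character(1))
  if (anyDuplicated(nm)) stop_design("pair names must be unique")
  names(pairs) <- nm
  structure(pairs, class = "paired_design")
}

#' @rdname paired_design
#' @param pair_name Label for the pair (e.g. `"MM"`, `"MCL"`).
#' @param sensitive,resistant Character vectors of sample identifiers.
#' @export
design_pair <- function(pair_name, sensitive, resistant) {
  sensitive <- as.character(sensitive)
  resistant <- as.character(resistant)
  if (length(sensitive) < 1 || length(resistant) < 1) {
    stop_design(sprintf("pair '%s': both groups must be nonempty", pair_name))
  }
  overlap <- intersect(sensitive, resistant)
  if (length(overlap) > 0) {
    stop_design(sprintf("pair '%s': sample(s) in both groups: %s",
                        pair_name, paste(overlap, collapse = ", ")))
  }
  structure(list(pair_name = as.character(pair_name),
                 sensitive = sensitive, resistant = resistant),
            class = "design_pair")
}

#' @export
print.paired_design <- function(x, ...) {
  cat(sprintf("<paired_design> %d pair(s)\n", length(x)))
  for (p in x) {
    cat(sprintf("  %s: %d sensitive vs %d resistant\n",
                p$pair_name, length(p$sensitive), length(p$resistant)))
  }
  invisible(x)
}

# all sample ids referenced by a design
design_samples <- function(design) {
  unique(unlist(lapply(design, function(p) c(p$sensitive, p$resistant))))
}
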