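# Tier-1 screen: per-probe Pearson correlation of log2 expression with
# log10(GI50) across a cell-line panel. Significance comes from the exact
# conversion t = r * sqrt(df) / sqrt(1 - r^2) with df = n_used - 2, followed
# by the two-tailed Student-t tail probability. Significant probes are split
# by the sign of r into resistance-associated (r > 0: high expression in
# lines with high GI50) and sensitivity-associated (r < 0) lists ranked by
# descending |r|.

#' Pearson correlation of two vectors (pairwise-complete)
#'
#' Computes the sample Pearson correlation after dropping incomplete pairs.
#' The screen treats a probe as degenerate (and skips it) when either vector
#' has zero variance or fewer than three complete pairs remain; this
#' function raises the corresponding classed error so callers can react.
#'
#' @param x,y Numeric vectors of equal length.
#' @return The correlation coefficient, clamped into `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop_contract("`x` and `y` must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) {
    abort(sprintf("fewer than 3 complete pairs (%d)", length(x)),
          class = "chemoscreen_insufficient_data")
  }
  if (var(x) == 0 || var(y) == 0) {
    stop_degenerate("zero variance: correlation undefined")
  }
  r <- cor(x, y)
  max(-1, min(1, r))
}

#' Convert a correlation coefficient to a Student-t statistic
#'
#' Applies `t = r * sqrt(df) / sqrt(1 - r^2)`, the exact relation between a
#' sample Pearson correlation and its t statistic under the bivariate-normal
#' null. With the full 60-line panel, `df = 58`.
#'
#' @param r Correlation coefficient(s) in `[-1, 1]`.
#' @param df Degrees of freedom, `n_used - 2`, at least 1.
#' @return t statistic(s), same sign as `r`. `|r| = 1` yields a signed
#'   infinity with a warning (the tail probability is then reported as the
#'   smallest representable positive value).
#' @examples
#' t_from_r(0.541833, 58)  # ~4.91
#' @export
t_from_r <- function(r, df) {
  if (any(!is.finite(r)) || any(abs(r) > 1)) {
    stop_value("`r` must be finite and within [-1, 1]")
  }
  if (any(df < 1)) stop_contract("`df` must be >= 1")
  out <- r * sqrt(df) / sqrt(1 - r^2)
  if (any(abs(r) == 1)) {
    warn("|r| = 1: t statistic is infinite; P will be flagged at machine resolution",
         class = "chemoscreen_infinite_statistic")
    out[abs(r) == 1] <- sign(r[abs(r) == 1]) * Inf
  }
  out
}

#' Two-tailed Student-t tail probability
#'
#' @param t t statistic(s).
#' @param df Degrees of freedom, at least 1 (`Inf` allowed: normal limit).
#' @return Two-tailed P in `(0, 1]`. Probabilities that underflow to zero
#'   (including infinite `t`) are reported as `.Machine$double.xmin`.
#' @examples
#' p_from_t(0, 58)      # 1
#' p_from_t(3.2557, 58) # ~0.00189
#' @export
p_from_t <- function(t, df) {
  if (any(df < 1)) stop_contract("`df` must be >= 1")
  p <- 2 * pt(abs(t), df, lower.tail = FALSE)
  p[!is.finite(t) | p <= 0] <- .Machine$double.xmin
  pmin(p, 1)
}

#' Run the panel-wide gene-drug correlation screen
#'
#' Correlates each probe's expression with `log10(GI50)` across the samples
#' shared between the expression matrix and the response profile, converts
#' each correlation to a two-tailed P value via [t_from_r()] and
#' [p_from_t()], and splits probes with `p_value < alpha` by the sign of `r`
#' into a resistance-associated and a sensitivity-associated list, each
#' ranked by descending `|r|` (ties broken by probe identifier). Probes with
#' zero variance or fewer than three complete pairs are skipped and
#' reported, not assigned `r = 0`.
#'
#' @param expr An [expr_matrix] on the log2 scale whose samples include all
#'   response samples.
#' @param response A [drug_response] profile.
#' @param alpha Two-tailed significance cutoff in `(0, 1)` (or exactly 1 to
#'   keep every probe); default 0.05.
#' @param annotation Optional [probe_gene_map()] tibble used to attach gene
#'   symbols.
#' @return An object of class `primary_screen` with elements
#'   \describe{
#'     \item{records}{tibble of all scored probes: `probe_id`, `gene_symbol`,
#'       `n_used`, `r`, `t_stat`, `df`, `p_value`}
#'     \item{resistance, sensitivity}{ranked significant sublists (columns as
#'       above plus `rank` and `direction`)}
#'     \item{skipped}{tibble of skipped probes with reasons}
#'     \item{alpha, n_samples}{screen parameters}
#'   }
#' @export
run_primary_screen <- function(expr, response, alpha = 0.05, annotation = NULL) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (!(alpha >= 0 && alpha <= 1)) stop_value("`alpha` must lie in [0, 1]")
  if (expr$scale != "log2") {
    warn("expression matrix is not flagged log2; the screen assumes log-scale values")
  }
  missing_samples <- setdiff(response$sample_id, sample_ids(expr))
  if (length(missing_samples) > 0) {
    stop_pipeline(sprintf("response sample(s) absent from expression matrix: %s",
                          paste(head(missing_samples, 5), collapse = ", ")))
  }
  shared <- response$sample_id
  if (length(shared) < 3) {
    stop_pipeline("fewer than 3 overlapping samples between expression and response")
  }
  v <- expr$values[, shared, drop = FALSE]
  y <- response$log10_gi50[match(shared, response$sample_id)]

  score_probe <- function(x) {
    keep <- is.finite(x) & is.finite(y)
    n <- sum(keep)
    if (n < 3) return(c(NA_real_, n, 1))         # r, n_used, skip code
    if (var(x[keep]) == 0 || var(y[keep]) == 0) return(c(NA_real_, n, 2))
    c(max(-1, min(1, cor(x[keep], y[keep]))), n, 0)
  }
  scored <- t(apply(v, 1, score_probe))
  skip_code <- scored[, 3]
  skipped <- tibble(
    probe_id = rownames(v)[skip_code != 0],
    reason = c("insufficient_data", "zero_variance")[skip_code[skip_code != 0]]
  )
  ok <- skip_code == 0
  r <- unname(scored[ok, 1])
  n_used <- as.integer(unname(scored[ok, 2]))
  df <- n_used - 2L
  t_stat <- suppressWarnings(withCallingHandlers(
    t_from_r(r, df),
    chemoscreen_infinite_statistic = function(w) invokeRestart("muffleWarning")
  ))
  records <- tibble(
    probe_id = rownames(v)[ok],
    gene_symbol = NA_character_,
    n_used = n_used, r = r, t_stat = t_stat, df = df,
    p_value = p_from_t(t_stat, df)
  )
  if (!is.null(annotation)) {
    records$gene_symbol <- annotation$gene_symbol[
      match(records$probe_id, annotation$probe_id)]
  }
  if (nrow(records) == 0) {
    warn("all probes were degenerate: empty screen result")
  }

  take_direction <- function(sign_fun, label) {
    out <- dplyr::filter(records, .data$p_value < alpha, sign_fun(.data$r))
    out <- dplyr::arrange(out, dplyr::desc(abs(.data$r)), .data$probe_id)
    dplyr::mutate(out, rank = dplyr::row_number(), direction = label)
  }
  structure(list(
    records = records,
    resistance = take_direction(function(r) r > 0, "resistance_associated"),
    sensitivity = take_direction(function(r) r < 0, "sensitivity_associated"),
    skipped = skipped,
    alpha = alpha,
    n_samples = length(shared)
  ), class = "primary_screen")
}

#' @export
print.primary_screen <- function(x, ...) {
  cat(sprintf(paste0("<primary_screen> %d probes over %d samples (alpha = %g)\n",
                     "  resistance-associated: %d probes; sensitivity-associated: %d probes",
                     "; skipped: %d\n"),
              nrow(x$records), x$n_samples, x$alpha,
              nrow(x$resistance), nrow(x$sensitivity), nrow(x$skipped)))
  invisible(x)
}

# Collapse significant probes to distinct gene symbols per direction,
# removing (and reporting) genes whose probes land in both directions.
collapse_by_direction <- function(pos_genes, neg_genes) {
  pos <- unique(pos_genes)
  neg <- unique(neg_genes)
  conflicts <- intersect(pos, neg)
  list(positive = setdiff(pos, conflicts),
       negative = setdiff(neg, conflicts),
       conflicts = conflicts)
}

#' Collapse a primary screen's significant probes to unique transcripts
#'
#' Maps each significant probe to its gene symbol and reduces the two
#' directional lists to sets of distinct genes. A gene with probes in both
#' directions is removed from both sets and reported as conflicting.
#'
#' @param screen A `primary_screen` object from [run_primary_screen()].
#' @param annotation A [probe_gene_map()] tibble covering every significant
#'   probe.
#' @return A list with two [gene_signature] objects (`sensitivity`,
#'   `resistance`, screen label `"primary_panel"`) and a character vector
#'   `conflicts`.
#' @export
collapse_unique_transcripts <- function(screen, annotation) {
  stopifnot(inherits(screen, "primary_screen"))
  lookup <- function(probes) {
    idx <- match(probes, annotation$probe_id)
    if (anyNA(idx)) {
      stop_annotation(sprintf("unmapped probe(s): %s",
                              paste(head(probes[is.na(idx)], 5), collapse = ", ")))
    }
    annotation$gene_symbol[idx]
  }
  sets <- collapse_by_direction(lookup(screen$resistance$probe_id),
                                lookup(screen$sensitivity$probe_id))
  if (length(sets$conflicts) > 0) {
    inform(sprintf("gene(s) with sign-conflicting probes excluded from both directions: %s",
                   paste(sets$conflicts, collapse = ", ")))
  }
  list(
    sensitivity = gene_signature(sets$negative, screen = "primary_panel",
                                 direction = "sensitivity_associated"),
    resistance = gene_signature(sets$positive, screen = "primary_panel",
                                direction = "resistance_associated"),
    conflicts = sets$conflicts
  )
}
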