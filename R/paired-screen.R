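# Tier-2 screen: detection filtering, log2 + quantile normalization,
# empirical-Bayes moderated per-pair contrasts, Benjamini-Hochberg FDR on
# the intersection-union (max over pairs) P value, and the strictly-greater
# 1.5-fold directionally-congruent filter that both pairs must pass.

#' Filter probes by detection P value
#'
#' Retains probes called "present" (detection `P < detection_alpha`) in at
#' least one sample; everything else is dropped as background. The number of
#' retained probes is reported via a message.
#'
#' @param expr An [expr_matrix] carrying a detection-P grid.
#' @param detection_alpha Detection cutoff in `(0, 1)`; default 0.01.
#' @return The filtered [expr_matrix].
#' @export
detection_filter <- function(expr, detection_alpha = 0.01) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (is.null(expr$detection_p)) {
    stop_config("no detection-P grid present; disable the detection filter explicitly instead")
  }
  if (!(detection_alpha > 0 && detection_alpha < 1)) {
    stop_value("`detection_alpha` must lie in (0, 1)")
  }
  keep <- rowSums(expr$detection_p < detection_alpha, na.rm = TRUE) >= 1
  inform(sprintf("detection filter: %d of %d probes retained (P < %g in >= 1 sample)",
                 sum(keep), length(keep), detection_alpha))
  subset_expr(expr, probes = probe_ids(expr)[keep])
}

#' Log2 transform and quantile-normalize an expression matrix
#'
#' Transforms raw positive intensities to log2 and applies full quantile
#' normalization across samples (after which every sample shares the same
#' sorted value vector). Delegates the normalization to
#' [limma::normalizeQuantiles()].
#'
#' @param expr A raw-scale [expr_matrix] with strictly positive intensities.
#' @return An [expr_matrix] on the log2 scale; the detection grid is carried
#'   through unchanged.
#' @export
normalize_log_quantile <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (expr$scale != "raw") {
    stop_contract("`expr` must be raw-scale intensities (scale = \"raw\")")
  }
  if (any(expr$values <= 0, na.rm = TRUE)) {
    stop_value("nonpositive intensity: configure an offset explicitly before normalizing")
  }
  norm <- limma::normalizeQuantiles(log2(expr$values))
  dimnames(norm) <- dimnames(expr$values)
  expr_matrix(norm, detection_p = expr$detection_p, scale = "log2")
}

# Inverse of trigamma by Newton iteration (monotone decreasing on (0, Inf)).
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Estimate empirical-Bayes variance-moderation hyperparameters
#'
#' Moment-matches the spread of log residual variances against the scaled-F
#' model in which each probe's sample variance is `sigma^2 * chisq(d)/d` and
#' `sigma^2` follows a scaled inverse-chi-square prior with `prior_df`
#' degrees of freedom and scale `prior_var`. If the observed spread of log
#' variances is no wider than the chi-square sampling spread alone, there is
#' no evidence of variance heterogeneity and the prior is taken as
#' degenerate: `prior_df = Inf` with `prior_var` the mean variance.
#'
#' @param residual_vars Nonnegative per-probe residual variances (at least
#'   50 probes).
#' @param residual_df Residual degrees of freedom `d` shared by the
#'   variances, at least 1.
#' @return An object of class `moderation_params`: list with `prior_df` and
#'   `prior_var`.
#' @export
estimate_moderation <- function(residual_vars, residual_df) {
  if (length(residual_vars) < 50) {
    stop_contract("need at least 50 probes to estimate moderation hyperparameters")
  }
  if (residual_df < 1) stop_contract("`residual_df` must be >= 1")
  if (any(!is.finite(residual_vars)) || any(residual_vars < 0)) {
    stop_value("residual variances must be finite and >= 0")
  }
  pos <- residual_vars[residual_vars > 0]
  if (length(pos) == 0) stop_degenerate("all residual variances are zero")
  if (length(pos) < length(residual_vars)) {
    warn(sprintf("%d zero variance(s) excluded from hyperparameter estimation",
                 length(residual_vars) - length(pos)))
  }
  d <- residual_df
  z <- log(pos)
  evar <- var(z) - trigamma(d / 2)
  if (is.finite(evar) && evar > 0) {
    prior_df <- 2 * trigamma_inverse(evar)
    prior_var <- exp(mean(z) - digamma(d / 2) + log(d / 2) +
                       digamma(prior_df / 2) - log(prior_df / 2))
  } else {
    prior_df <- Inf
    prior_var <- mean(residual_vars)
  }
  structure(list(prior_df = prior_df, prior_var = prior_var),
            class = "moderation_params")
}

#' @export
print.moderation_params <- function(x, ...) {
  cat(sprintf("<moderation_params> prior_df = %g, prior_var = %g\n",
              x$prior_df, x$prior_var))
  invisible(x)
}

#' Moderated per-pair differential test
#'
#' For every probe, computes the sensitive-minus-resistant contrast within
#' each pair using a residual variance pooled across all design groups and
#' shrunk toward the empirical-Bayes prior:
#' `v_mod = (prior_df * prior_var + d * s^2) / (prior_df + d)`, tested on
#' `prior_df + d` degrees of freedom. The per-probe combined P value is the
#' maximum of the per-pair P values (an intersection-union test: both pairs
#' must deviate), and Benjamini-Hochberg q-values are computed on it.
#'
#' @param expr A normalized log2 [expr_matrix].
#' @param design A [paired_design]; every group needs at least 2 replicates
#'   present in `expr`.
#' @param params Optional [estimate_moderation()] result; estimated from the
#'   pooled residual variances when `NULL`. `prior_df = 0` gives the
#'   ordinary pooled-variance t test.
#' @param annotation Optional [probe_gene_map()] tibble for gene symbols.
#' @return An object of class `paired_screen` with elements
#'   \describe{
#'     \item{records}{per-probe tibble: `probe_id`, `gene_symbol`,
#'       `combined_p`, `fdr_q`, `direction` (`higher_in_sensitive`,
#'       `higher_in_resistant` or `none`)}
#'     \item{per_pair}{per-probe-per-pair tibble: `log2_fc` (sensitive minus
#'       resistant), linear `fold_change = 2^log2_fc`, `t`, `p`}
#'     \item{params}{the moderation hyperparameters used}
#'     \item{residual_df}{pooled residual degrees of freedom `d`}
#'   }
#' @export
moderated_pair_test <- function(expr, design, params = NULL, annotation = NULL) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(design, "paired_design"))
  if (expr$scale != "log2") stop_contract("`expr` must be on the log2 scale")
  all_ids <- design_samples(design)
  missing_ids <- setdiff(all_ids, sample_ids(expr))
  if (length(missing_ids) > 0) {
    stop_design(sprintf("design sample(s) absent from expression matrix: %s",
                        paste(head(missing_ids, 5), collapse = ", ")))
  }
  groups <- list()
  for (p in design) {
    if (length(p$sensitive) < 2 || length(p$resistant) < 2) {
      stop_design(sprintf("pair '%s': every group needs >= 2 replicates", p$pair_name))
    }
    groups[[paste0(p$pair_name, ".sensitive")]] <- p$sensitive
    groups[[paste0(p$pair_name, ".resistant")]] <- p$resistant
  }
  v <- expr$values
  if (anyNA(v[, all_ids])) {
    stop_value("missing values in design samples: the paired test needs complete replicates")
  }
  n_g <- lengths(groups)
  d <- sum(n_g) - length(groups)
  means <- vapply(groups, function(ids) rowMeans(v[, ids, drop = FALSE]),
                  numeric(nrow(v)))
  ss <- vapply(seq_along(groups), function(i) {
    rowSums((v[, groups[[i]], drop = FALSE] - means[, i])^2)
  }, numeric(nrow(v)))
  s2 <- rowSums(ss) / d

  if (is.null(params)) params <- estimate_moderation(s2, d)
  stopifnot(inherits(params, "moderation_params"))
  d0 <- params$prior_df
  s0 <- params$prior_var
  v_mod <- if (is.infinite(d0)) rep(s0, length(s2)) else (d0 * s0 + d * s2) / (d0 + d)
  df_mod <- d0 + d

  per_pair <- purrr::map_dfr(design, function(p) {
    m_s <- means[, paste0(p$pair_name, ".sensitive")]
    m_r <- means[, paste0(p$pair_name, ".resistant")]
    diff <- unname(m_s - m_r)
    se <- sqrt(v_mod * (1 / length(p$sensitive) + 1 / length(p$resistant)))
    t <- unname(ifelse(se > 0, diff / se, ifelse(diff == 0, 0, Inf * sign(diff))))
    tibble(probe_id = rownames(v), pair = p$pair_name,
           log2_fc = diff, fold_change = 2^diff,
           t = t, p = p_from_t(t, df_mod))
  })

  dir_tab <- per_pair |>
    dplyr::group_by(.data$probe_id) |>
    dplyr::summarise(
      combined_p = max(.data$p),
      direction = dplyr::case_when(
        all(.data$log2_fc > 0) ~ "higher_in_sensitive",
        all(.data$log2_fc < 0) ~ "higher_in_resistant",
        TRUE ~ "none"),
      .groups = "drop") |>
    dplyr::arrange(match(.data$probe_id, rownames(v)))

  records <- tibble(
    probe_id = dir_tab$probe_id,
    gene_symbol = if (is.null(annotation)) NA_character_ else
      annotation$gene_symbol[match(dir_tab$probe_id, annotation$probe_id)],
    combined_p = dir_tab$combined_p,
    fdr_q = bh_fdr(dir_tab$combined_p),
    direction = dir_tab$direction
  )
  structure(list(records = records, per_pair = per_pair,
                 params = params, residual_df = d),
            class = "paired_screen")
}

#' @export
print.paired_screen <- function(x, ...) {
  cat(sprintf(paste0("<paired_screen> %d probes, %d pair(s), residual df = %d\n",
                     "  moderation: prior_df = %g, prior_var = %g\n"),
              nrow(x$records), length(unique(x$per_pair$pair)), x$residual_df,
              x$params$prior_df, x$params$prior_var))
  invisible(x)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: on sorted p-values,
#' `q(i) = min over j >= i of m * p(j) / j`, mapped back to input order and
#' capped at 1. Delegates to [stats::p.adjust()] after validating the input
#' range.
#'
#' @param p_values Numeric vector of p-values in `(0, 1]`.
#' @return q-values in `(0, 1]`, in input order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values <= 0 | p_values > 1)) {
    stop_value("p-values must lie in (0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Directionally-congruent fold-change filter
#'
#' A probe passes when, in every pair, the change has the same direction and
#' the linear fold change is strictly greater than `fc_min` (or strictly
#' less than `1/fc_min`) with per-pair raw `p < raw_alpha`, and the combined
#' FDR q-value is below `q_alpha`. Passing probes are collapsed to gene sets
#' by direction (higher in sensitive lines -> sensitivity-associated; higher
#' in resistant lines -> resistance-associated); genes with probes passing
#' in both directions are excluded from both sets and reported.
#'
#' @param screen A `paired_screen` from [moderated_pair_test()].
#' @param fc_min Linear fold-change threshold, > 1; default 1.5. A fold
#'   change exactly equal to `fc_min` fails.
#' @param raw_alpha Per-pair raw P cutoff; default 0.01.
#' @param q_alpha FDR cutoff on the combined P; default 0.05.
#' @param annotation Optional [probe_gene_map()] used if the screen records
#'   carry no gene symbols.
#' @return A list with [gene_signature] objects `sensitivity` and
#'   `resistance` (screen label `"paired_lines"`), the `conflicts` character
#'   vector, and a `passing` tibble of probes that met every criterion.
#' @export
congruence_filter <- function(screen, fc_min = 1.5, raw_alpha = 0.01,
                              q_alpha = 0.05, annotation = NULL) {
  stopifnot(inherits(screen, "paired_screen"))
  if (!(fc_min > 1)) stop_value("`fc_min` must be > 1")
  records <- screen$records
  if (all(is.na(records$gene_symbol))) {
    if (is.null(annotation)) {
      stop_annotation("no gene symbols available: supply `annotation`")
    }
    records$gene_symbol <- annotation$gene_symbol[
      match(records$probe_id, annotation$probe_id)]
  }
  pair_pass <- screen$per_pair |>
    dplyr::group_by(.data$probe_id) |>
    dplyr::summarise(
      all_up = all(.data$fold_change > fc_min),
      all_down = all(.data$fold_change < 1 / fc_min),
      all_sig = all(.data$p < raw_alpha),
      .groups = "drop")
  passing <- records |>
    dplyr::left_join(pair_pass, by = "probe_id") |>
    dplyr::filter(
      .data$direction != "none",
      (.data$all_up & .data$direction == "higher_in_sensitive") |
        (.data$all_down & .data$direction == "higher_in_resistant"),
      .data$all_sig,
      .data$fdr_q < q_alpha)
  unmapped <- passing$probe_id[is.na(passing$gene_symbol)]
  if (length(unmapped) > 0) {
    stop_annotation(sprintf("unmapped probe(s): %s",
                            paste(head(unmapped, 5), collapse = ", ")))
  }
  sets <- collapse_by_direction(
    passing$gene_symbol[passing$direction == "higher_in_resistant"],
    passing$gene_symbol[passing$direction == "higher_in_sensitive"])
  if (length(sets$conflicts) > 0) {
    inform(sprintf("gene(s) passing in both directions excluded: %s",
                   paste(sets$conflicts, collapse = ", ")))
  }
  list(
    sensitivity = gene_signature(sets$negative, screen = "paired_lines",
                                 direction = "sensitivity_associated"),
    resistance = gene_signature(sets$positive, screen = "paired_lines",
                                direction = "resistance_associated"),
    conflicts = sets$conflicts,
    passing = dplyr::select(passing, "probe_id", "gene_symbol",
                            "combined_p", "fdr_q", "direction")
  )
}
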