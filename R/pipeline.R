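# End-to-end orchestration: panel correlation screen -> paired moderated
# screen -> directional signature intersection, driven by one configuration
# (a YAML file or an equivalent nested list), with a machine-readable run
# manifest. Reruns on identical inputs are byte-identical: the manifest
# records input/output checksums, thresholds and versions but no
# timestamps.

default_thresholds <- function() {
  list(alpha = 0.05, detection_alpha = 0.01,
       fc_min = 1.5, raw_alpha = 0.01, q_alpha = 0.05)
}

#' Run the two-tier integrative screen end-to-end
#'
#' Reads the panel inputs (expression, GI50 response, annotation) and the
#' paired inputs (expression with optional detection grid, design,
#' annotation), runs the tier-1 correlation screen, the tier-2 moderated
#' paired screen with the directionally-congruent fold-change filter, and
#' intersects the resulting directional gene signatures. Writes the ranked
#' correlation tables, the per-probe differential table, the integrated
#' signature and a JSON manifest to `out_dir`.
#'
#' @param config Path to a YAML configuration or an equivalent nested list
#'   with entries:
#'   \describe{
#'     \item{panel}{`expression`, `response`, `annotation` paths}
#'     \item{paired}{`expression`, `design` paths; optional `detection`
#'       (detection-P grid; omit only with `detection_filter: false`),
#'       `annotation`, and logicals `normalize` (default `TRUE`: input is
#'       raw-scale and is log2/quantile-normalized) and `detection_filter`
#'       (default `TRUE`)}
#'     \item{thresholds}{optional overrides of `alpha = 0.05`,
#'       `detection_alpha = 0.01`, `fc_min = 1.5`, `raw_alpha = 0.01`,
#'       `q_alpha = 0.05`}
#'     \item{out_dir}{output directory (may also be given as the `out_dir`
#'       argument)}
#'   }
#' @param out_dir Output directory; overrides the config entry.
#' @return The `integrated_signature`, invisibly, with attributes
#'   `manifest` (the manifest list) and `files` (paths written).
#' @export
run_two_tier_screen <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_config(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_config("`config` must be a path or a nested list")
  for (section in c("panel", "paired")) {
    if (is.null(config[[section]])) {
      stop_config(sprintf("config lacks the `%s` section", section))
    }
  }
  thresholds <- utils::modifyList(default_thresholds(),
                                  config$thresholds %||% list())
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stop_config("no output directory given")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop_pipeline(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
                    parent = e)
    })
  }

  # ---- tier 1: panel correlation screen ----
  panel <- config$panel
  panel_annot <- run_stage("panel_inputs", read_probe_gene_map(panel$annotation))
  primary <- run_stage("primary_screen", {
    expr <- read_expression_matrix(panel$expression,
                                   dialect = panel$dialect %||% "tsv")
    response <- read_drug_response(panel$response)
    run_primary_screen(expr, response, alpha = thresholds$alpha,
                       annotation = panel_annot)
  })
  panel_sets <- run_stage("collapse_transcripts",
                          collapse_unique_transcripts(primary, panel_annot))

  # ---- tier 2: paired differential screen ----
  paired_cfg <- config$paired
  paired <- run_stage("paired_screen", {
    do_filter <- paired_cfg$detection_filter %||% TRUE
    expr <- read_expression_matrix(
      paired_cfg$expression, dialect = paired_cfg$dialect %||% "tsv",
      detection_path = paired_cfg$detection,
      scale = if (isTRUE(paired_cfg$normalize %||% TRUE)) "raw" else "log2")
    if (do_filter) expr <- detection_filter(expr, thresholds$detection_alpha)
    if (isTRUE(paired_cfg$normalize %||% TRUE)) expr <- normalize_log_quantile(expr)
    design <- read_paired_design(paired_cfg$design)
    annot <- if (is.null(paired_cfg$annotation)) panel_annot else
      read_probe_gene_map(paired_cfg$annotation)
    screen <- moderated_pair_test(expr, design, annotation = annot)
    congruence_filter(screen, fc_min = thresholds$fc_min,
                      raw_alpha = thresholds$raw_alpha,
                      q_alpha = thresholds$q_alpha) |>
      c(list(screen = screen))
  })

  # ---- tier 3: integration ----
  signature <- run_stage("integration", intersect_signatures(
    panel_sets$sensitivity, panel_sets$resistance,
    paired$sensitivity, paired$resistance))

  # ---- outputs ----
  files <- c(
    panel_resistance = file.path(out_dir, "panel_resistance.tsv"),
    panel_sensitivity = file.path(out_dir, "panel_sensitivity.tsv"),
    paired_differential = file.path(out_dir, "paired_differential.tsv"),
    integrated_signature = file.path(out_dir, "integrated_signature.tsv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_correlation_table(primary$resistance, files[["panel_resistance"]])
  write_correlation_table(primary$sensitivity, files[["panel_sensitivity"]])

  diff_tab <- paired$screen$per_pair |>
    tidyr::pivot_wider(id_cols = "probe_id", names_from = "pair",
                       values_from = c("log2_fc", "fold_change", "p")) |>
    dplyr::left_join(paired$screen$records, by = "probe_id") |>
    dplyr::mutate(pass = .data$probe_id %in% paired$passing$probe_id)
  num_cols <- vapply(diff_tab, is.numeric, logical(1))
  diff_out <- diff_tab
  diff_out[num_cols] <- lapply(diff_out[num_cols], fmt_num)
  utils::write.table(diff_out, files[["paired_differential"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)

  sig_tab <- tidy(signature)
  utils::write.table(sig_tab, files[["integrated_signature"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)

  input_paths <- c(panel$expression, panel$response, panel$annotation,
                   paired_cfg$expression, paired_cfg$detection,
                   paired_cfg$design, paired_cfg$annotation)
  input_paths <- input_paths[!vapply(input_paths, is.null, logical(1))]
  input_paths <- unlist(input_paths)
  manifest <- list(
    package = "chemoscreen",
    version = as.character(utils::packageVersion("chemoscreen")),
    thresholds = thresholds,
    seed = config$seed,
    inputs = as.list(tools::md5sum(input_paths)),
    outputs = as.list(tools::md5sum(unname(files[names(files) != "manifest"]))),
    n_panel_samples = primary$n_samples,
    n_panel_probes = nrow(primary$records),
    n_paired_probes = nrow(paired$screen$records),
    signature = list(sensitivity = signature$sensitivity_overlap,
                     resistance = signature$resistance_overlap)
  )
  jsonlite::write_json(manifest, files[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  attr(signature, "manifest") <- manifest
  attr(signature, "files") <- files
  invisible(signature)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
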