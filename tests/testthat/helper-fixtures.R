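# Shared fixture builders. Everything is generated in code; no binary data.

tiny_expr <- function(values = matrix(c(1, 2, 3, 4), 2, 2),
                      probes = c("p1", "p2"), samples = c("s1", "s2"),
                      ...) {
  dimnames(values) <- list(probes, samples)
  expr_matrix(values, ...)
}

# write a probes-as-rows TSV by hand (independent of the package writer)
write_tsv_fixture <- function(header, rows, path = withr::local_tempfile(
                                fileext = ".tsv", .local_envir = parent.frame())) {
  writeLines(c(paste(header, collapse = "\t"),
               vapply(rows, paste, character(1), collapse = "\t")), path)
  path
}

# rows of the ranked correlation tables printed for the 60-line panel,
# shipped as plain-text package data
panel_table <- function(direction = c("resistance", "sensitivity")) {
  direction <- match.arg(direction)
  read_correlation_table(system.file(
    "extdata", sprintf("panel_top50_%s.tsv", direction),
    package = "chemoscreen"))
}

# a small paired experiment with known planted genes, shared across tests
demo_paired <- function(n_probes = 400, seed = 42, ...) {
  simulate_paired_experiment(
    n_probes = n_probes,
    planted = tibble::tibble(gene_symbol = c("UPGENE", "DOWNGENE"),
                             log2_fc = c(1.5, -1.5)),
    seed = seed, ...)
}

# brute-force Benjamini-Hochberg step-up q-values (double loop), used as
# the independent oracle for bh_fdr()
bh_brute_force <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) {
      cand <- (m / j) * p[ord[j]]
      if (cand < best) best <- cand
    }
    q[ord[i]] <- min(best, 1)
  }
  q
}

# Write a complete two-tier screen input set (panel + paired + config) to
# `dir` with 1 sensitivity-associated and 6 resistance-associated genes
# planted to pass both tiers, and return the config path.
make_screen_config <- function(dir, seed = 1, panel_probes = 5007,
                               paired_probes = 5007, thresholds = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sens_genes <- "SENSG1"
  res_genes <- sprintf("RESG%d", 1:6)

  panel_planted <- tibble::tibble(
    probe_id = sprintf("PL%02d_at", 1:7),
    rho = c(-0.6, rep(0.6, 6)),
    gene_symbol = c(sens_genes, res_genes))
  panel <- simulate_panel(n_probes = panel_probes, planted = panel_planted,
                          seed = seed)
  paired_planted <- tibble::tibble(
    gene_symbol = c(sens_genes, res_genes),
    log2_fc = c(1.5, rep(-1.5, 6)))
  paired <- simulate_paired_experiment(n_probes = paired_probes,
                                       planted = paired_planted,
                                       seed = seed + 1)

  paths <- list(
    panel_expr = file.path(dir, "panel_expression.tsv"),
    panel_resp = file.path(dir, "panel_response.tsv"),
    panel_annot = file.path(dir, "panel_annotation.tsv"),
    paired_expr = file.path(dir, "paired_expression.tsv"),
    paired_det = file.path(dir, "paired_detection.tsv"),
    paired_annot = file.path(dir, "paired_annotation.tsv"),
    design = file.path(dir, "design.yaml"),
    config = file.path(dir, "config.yaml"))

  write_expression_matrix(panel$expr, paths$panel_expr)
  writeLines(c("sample_id\tgi50_molar",
               sprintf("%s\t%.17g", panel$response$sample_id,
                       panel$response$gi50_molar)), paths$panel_resp)
  writeLines(c("probe_id\tgene_symbol",
               sprintf("%s\t%s", panel$annotation$probe_id,
                       panel$annotation$gene_symbol)), paths$panel_annot)
  write_expression_matrix(paired$expr, paths$paired_expr,
                          detection_path = paths$paired_det)
  writeLines(c("probe_id\tgene_symbol",
               sprintf("%s\t%s", paired$annotation$probe_id,
                       paired$annotation$gene_symbol)), paths$paired_annot)
  yaml::write_yaml(list(pairs = lapply(paired$design, function(p) {
    list(name = p$pair_name, sensitive = p$sensitive, resistant = p$resistant)
  })), paths$design)

  config <- list(
    panel = list(expression = paths$panel_expr, response = paths$panel_resp,
                 annotation = paths$panel_annot),
    paired = list(expression = paths$paired_expr,
                  detection = paths$paired_det,
                  design = paths$design, annotation = paths$paired_annot),
    seed = seed,
    out_dir = file.path(dir, "out"))
  if (!is.null(thresholds)) config$thresholds <- thresholds
  yaml::write_yaml(config, paths$config)
  paths
}
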