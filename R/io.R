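# Readers and writers for the plain-text tabular formats every stage
# consumes: probes-as-rows expression TSVs (plus an optional companion
# detection-P grid), two-column GI50 tables, probe->gene annotation, a YAML
# paired-design description, and the ranked correlation-table schema
# (rank, probe_set_id, gene_symbol, r, p_value).
#
# Numeric cells are written with "%.17g" so that write -> read round-trips
# IEEE doubles bitwise; empty cells and "NA" are read back as missing.

# parse a character matrix of numeric cells, reporting the first offending
# cell by row/column name
parse_numeric_cells <- function(ch, what) {
  suppressWarnings(num <- array(as.numeric(ch), dim = dim(ch), dimnames = dimnames(ch)))
  bad <- which(is.na(num) & !(is.na(ch) | ch == "" | ch == "NA"), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_parse(sprintf(
      "%s: non-numeric cell '%s' at row '%s', column '%s'",
      what, ch[bad[1, 1], bad[1, 2]],
      rownames(ch)[bad[1, 1]], colnames(ch)[bad[1, 2]]))
  }
  num
}

read_delim_cells <- function(path, skip = 0) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t", skip = skip,
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, quote = "", comment.char = "")
  df
}

#' Read a probe-by-sample expression matrix
#'
#' Reads a tab-separated expression table (first column probe identifiers,
#' header row sample identifiers, numeric body) into an [expr_matrix]. The
#' `gct_like` dialect skips two leading header lines and drops a
#' `Description` column if one follows the identifier column. An optional
#' companion detection-P file of identical shape can be attached.
#'
#' @param path Path to the expression TSV.
#' @param dialect `"tsv"` (plain, default) or `"gct_like"`.
#' @param detection_path Optional path to a detection-P TSV of identical
#'   layout.
#' @param scale Scale flag recorded on the result: `"log2"` or `"raw"`.
#' @return An [expr_matrix]. Missing cells (empty or `NA`) are recorded as
#'   `NA`, never as zero.
#' @export
read_expression_matrix <- function(path, dialect = c("tsv", "gct_like"),
                                   detection_path = NULL,
                                   scale = c("log2", "raw")) {
  dialect <- match.arg(dialect)
  scale <- match.arg(scale)
  skip <- if (dialect == "gct_like") 2L else 0L
  df <- read_delim_cells(path, skip = skip)
  if (ncol(df) < 2) stop_format(sprintf("%s: expected probe column plus samples", path))
  if (dialect == "gct_like" && ncol(df) >= 2 &&
      tolower(names(df)[2]) == "description") {
    df <- df[, -2, drop = FALSE]
  }
  probes <- df[[1]]
  dup <- unique(probes[duplicated(probes)])
  if (length(dup) > 0) {
    stop_format(sprintf("%s: duplicate probe identifier(s): %s",
                        path, paste(head(dup, 5), collapse = ", ")))
  }
  samples <- names(df)[-1]
  dups <- unique(samples[duplicated(samples)])
  if (length(dups) > 0) {
    stop_format(sprintf("%s: duplicate sample identifier(s): %s",
                        path, paste(head(dups, 5), collapse = ", ")))
  }
  ch <- as.matrix(df[, -1, drop = FALSE])
  rownames(ch) <- probes
  vals <- parse_numeric_cells(ch, path)
  detection <- NULL
  if (!is.null(detection_path)) {
    dp <- read_expression_matrix(detection_path, dialect = dialect)
    if (!identical(dim(dp$values), dim(vals)) ||
        !identical(rownames(dp$values), probes) ||
        !identical(colnames(dp$values), samples)) {
      stop_format("detection-P grid does not match the expression matrix layout")
    }
    detection <- dp$values
  }
  expr_matrix(vals, detection_p = detection, scale = scale)
}

fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))

#' Write an expression matrix (and optionally its detection grid)
#'
#' @param x An [expr_matrix].
#' @param path Output TSV path.
#' @param detection_path Optional path for the companion detection-P TSV.
#' @return `x`, invisibly.
#' @export
write_expression_matrix <- function(x, path, detection_path = NULL) {
  write_grid <- function(m, p) {
    body <- apply(m, 2, fmt_num)
    if (is.null(dim(body))) body <- matrix(body, nrow = nrow(m))
    lines <- c(paste(c("probe_id", colnames(m)), collapse = "\t"),
               paste(rownames(m), apply(body, 1, paste, collapse = "\t"),
                     sep = "\t"))
    writeLines(lines, p)
  }
  write_grid(x$values, path)
  if (!is.null(detection_path)) {
    if (is.null(x$detection_p)) stop_contract("no detection grid to write")
    write_grid(x$detection_p, detection_path)
  }
  invisible(x)
}

#' Read a per-sample drug response table
#'
#' Expects a two-column TSV `sample_id<TAB>gi50_molar` with GI50 in molar
#' units; the base-10 log is computed on read.
#'
#' @param path Path to the TSV.
#' @return A [drug_response] tibble.
#' @export
read_drug_response <- function(path) {
  df <- read_delim_cells(path)
  if (ncol(df) < 2) stop_format(sprintf("%s: expected sample_id and gi50_molar columns", path))
  ch <- as.matrix(df[, 2, drop = FALSE])
  rownames(ch) <- df[[1]]
  gi50 <- drop(parse_numeric_cells(ch, path))
  drug_response(df[[1]], as.numeric(gi50))
}

#' Read a probe-to-gene annotation table
#'
#' Expects a two-column TSV `probe_id<TAB>gene_symbol`.
#'
#' @param path Path to the TSV.
#' @return A validated annotation tibble (see [probe_gene_map()]).
#' @export
read_probe_gene_map <- function(path) {
  df <- read_delim_cells(path)
  if (ncol(df) < 2) stop_format(sprintf("%s: expected probe_id and gene_symbol columns", path))
  probe_gene_map(df[[1]], df[[2]])
}

#' Read a paired design from a YAML description
#'
#' The file lists pairs of sensitive/resistant sample groups:
#' ```yaml
#' pairs:
#'   - name: MM
#'     sensitive: [MM1S_1, MM1S_2, MM1S_3]
#'     resistant: [U266_1, U266_2, U266_3]
#' ```
#' @param path Path to the YAML file.
#' @return A [paired_design].
#' @export
read_paired_design <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  y <- yaml::read_yaml(path)
  if (is.null(y$pairs)) stop_format(sprintf("%s: no `pairs` section", path))
  pairs <- lapply(y$pairs, function(p) {
    design_pair(p$name, sensitive = unlist(p$sensitive),
                resistant = unlist(p$resistant))
  })
  paired_design(pairs)
}

correlation_table_cols <- c("rank", "probe_set_id", "gene_symbol", "r", "p_value")

#' Write a ranked correlation table
#'
#' Writes the ranked output of the tier-1 screen in the five-column schema
#' `rank, probe_set_id, gene_symbol, r, p_value`, in rank order.
#'
#' @param records A tibble with at least columns `rank`, `probe_id` (or
#'   `probe_set_id`), `gene_symbol`, `r` and `p_value`, already ranked
#'   (`rank` must equal `1..n` in row order).
#' @param path Output TSV path.
#' @return `records`, invisibly.
#' @export
write_correlation_table <- function(records, path) {
  records <- as_tibble(records)
  if (!"probe_set_id" %in% names(records) && "probe_id" %in% names(records)) {
    records <- dplyr::rename(records, probe_set_id = "probe_id")
  }
  missing_cols <- setdiff(correlation_table_cols, names(records))
  if (length(missing_cols) > 0) {
    stop_contract(sprintf("correlation records lack column(s): %s",
                          paste(missing_cols, collapse = ", ")))
  }
  if (!identical(as.integer(records$rank), seq_len(nrow(records)))) {
    stop_contract("records must be ranked: `rank` must equal 1..n in row order")
  }
  out <- records[, correlation_table_cols]
  lines <- c(paste(correlation_table_cols, collapse = "\t"),
             vapply(seq_len(nrow(out)), function(i) {
               paste(c(as.character(out$rank[i]), out$probe_set_id[i],
                       out$gene_symbol[i], fmt_num(out$r[i]),
                       fmt_num(out$p_value[i])), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(records)
}

#' Read a ranked correlation table written by [write_correlation_table()]
#' @param path Path to the TSV.
#' @return A tibble with columns `rank`, `probe_set_id`, `gene_symbol`, `r`,
#'   `p_value`.
#' @export
read_correlation_table <- function(path) {
  df <- read_delim_cells(path)
  missing_cols <- setdiff(correlation_table_cols, names(df))
  if (length(missing_cols) > 0) {
    stop_format(sprintf("%s: missing column(s): %s", path,
                        paste(missing_cols, collapse = ", ")))
  }
  tibble(rank = as.integer(df$rank),
         probe_set_id = df$probe_set_id,
         gene_symbol = df$gene_symbol,
         r = as.numeric(df$r),
         p_value = as.numeric(df$p_value))
}
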