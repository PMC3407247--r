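# Seeded generators for every input the pipeline consumes, with the
# statistical structure the screens assume: a ~60-sample panel whose
# planted probes carry exact population correlations with the log10(GI50)
# phenotype, a replicated sensitive/resistant paired design with planted
# directionally-congruent fold changes over log-normal noise, and linear
# kinetic traces. All generators are pure functions of their arguments:
# the seed is an explicit argument and global RNG state is untouched.

#' Simulate a drug-screening panel with planted gene-drug correlations
#'
#' Draws a standard-normal phenotype z, maps it to plausible molar GI50s as
#' `log10(GI50) = -5.5 + 0.75 z`, and builds each planted probe as
#' `rho * z + sqrt(1 - rho^2) * noise` (so its population correlation with
#' the phenotype is exactly `rho`), rescaled to the baseline log2 intensity
#' distribution. Remaining probes are independent noise. Probes are
#' assigned to genes with `probes_per_gene` probes each, so many-to-one
#' probe-gene structure is present.
#'
#' @param n_probes Total number of probes.
#' @param n_samples Panel size; default 60.
#' @param planted Optional tibble/data frame with columns `probe_id` and
#'   `rho` (`|rho| < 1`), and optionally `gene_symbol`. Planted probes are
#'   included in `n_probes`.
#' @param baseline_mean,baseline_sd Mean and SD of log2 intensities;
#'   defaults 8 and 1.
#' @param probes_per_gene Number of consecutive probes sharing a gene
#'   symbol; default 1.
#' @param seed Integer seed; required for reproducibility.
#' @return List with `expr` ([expr_matrix], log2 scale), `response`
#'   ([drug_response]) and `annotation` ([probe_gene_map()] tibble).
#' @export
simulate_panel <- function(n_probes, n_samples = 60, planted = NULL,
                           baseline_mean = 8, baseline_sd = 1,
                           probes_per_gene = 1, seed) {
  stopifnot(n_probes >= 1, n_samples >= 3)
  if (!is.null(planted)) {
    planted <- as_tibble(planted)
    if (anyDuplicated(planted$probe_id)) stop_value("planted probe ids must be unique")
    if (any(abs(planted$rho) >= 1)) stop_value("planted |rho| must be < 1")
    if (nrow(planted) > n_probes) stop_value("more planted probes than `n_probes`")
  }
  withr::with_seed(seed, {
    z <- rnorm(n_samples)
    log10_gi50 <- -5.5 + 0.75 * z
    sample_id <- sprintf("CL%02d", seq_len(n_samples))
    response <- drug_response(sample_id, 10^log10_gi50)

    n_planted <- if (is.null(planted)) 0L else nrow(planted)
    null_ids <- sprintf("P%05d_at", seq_len(n_probes - n_planted))
    vals <- matrix(rnorm((n_probes - n_planted) * n_samples), ncol = n_samples)
    probe_id <- null_ids
    if (n_planted > 0) {
      pv <- vapply(planted$rho, function(rho) {
        rho * z + sqrt(1 - rho^2) * rnorm(n_samples)
      }, numeric(n_samples))
      vals <- rbind(t(pv), vals)
      probe_id <- c(planted$probe_id, null_ids)
    }
    vals <- baseline_mean + baseline_sd * vals
    dimnames(vals) <- list(probe_id, sample_id)

    gene <- sprintf("GENE%05d", ceiling(seq_len(n_probes) / probes_per_gene))
    if (n_planted > 0 && "gene_symbol" %in% names(planted)) {
      gene[seq_len(n_planted)] <- planted$gene_symbol
    }
    list(expr = expr_matrix(vals, scale = "log2"),
         response = response,
         annotation = probe_gene_map(probe_id, gene))
  })
}

#' Simulate a replicated paired sensitive/resistant experiment
#'
#' Generates a raw-intensity expression matrix (log-normal: Gaussian on the
#' log2 scale, exponentiated) over `pairs` pairs of sensitive/resistant
#' groups with `replicates` samples each, plus a detection-P grid and a
#' probe-gene map. Planted genes are shifted by `log2_fc` in the sensitive
#' group of every pair (directionally congruent across pairs); all other
#' probes are null. A fraction of null probes is flagged "absent": their
#' detection P values are drawn uniformly above the detection threshold, so
#' a detection filter at that threshold removes exactly the absent set.
#'
#' @param n_probes Total number of probes.
#' @param planted Optional tibble with columns `gene_symbol` and `log2_fc`
#'   (nonzero; positive = higher in sensitive lines). Each planted gene gets
#'   `probes_per_gene` probes, included in `n_probes`.
#' @param pairs Number of pairs; default 2 (an MM-like and an MCL-like pair).
#' @param replicates Replicates per group; default 3.
#' @param probes_per_gene Probes per gene; default 1.
#' @param noise_sd Replicate noise SD on the log2 scale; default 0.25.
#' @param baseline_mean,baseline_sd Per-probe baseline log2 mean
#'   distribution; defaults 8 and 1.5.
#' @param absent_frac Fraction of null probes flagged absent; default 0.25.
#' @param detection_alpha Detection threshold the absent flags are defined
#'   against; default 0.01.
#' @param seed Integer seed.
#' @return List with `expr` (raw-scale [expr_matrix] with `detection_p`),
#'   `design` ([paired_design]) and `annotation` tibble.
#' @export
simulate_paired_experiment <- function(n_probes, planted = NULL, pairs = 2,
                                       replicates = 3, probes_per_gene = 1,
                                       noise_sd = 0.25, baseline_mean = 8,
                                       baseline_sd = 1.5, absent_frac = 0.25,
                                       detection_alpha = 0.01, seed) {
  stopifnot(n_probes >= 1, pairs >= 1, replicates >= 2)
  n_planted_probes <- 0L
  if (!is.null(planted)) {
    planted <- as_tibble(planted)
    if (anyDuplicated(planted$gene_symbol)) stop_value("planted genes must be unique")
    if (any(planted$log2_fc == 0)) stop_value("planted |log2_fc| must be > 0")
    n_planted_probes <- nrow(planted) * probes_per_gene
    if (n_planted_probes > n_probes) stop_value("more planted probes than `n_probes`")
  }
  pair_names <- c("MM", "MCL", sprintf("PAIR%d", seq_len(max(0, pairs - 2))))[seq_len(pairs)]
  design <- paired_design(lapply(pair_names, function(nm) {
    design_pair(nm,
                sensitive = sprintf("%s_S%d", nm, seq_len(replicates)),
                resistant = sprintf("%s_R%d", nm, seq_len(replicates)))
  }))
  samples <- design_samples(design)
  sens_cols <- unlist(lapply(design, function(p) p$sensitive))

  withr::with_seed(seed, {
    n_null <- n_probes - n_planted_probes
    probe_id <- sprintf("ILMN_%06d", seq_len(n_probes))
    gene <- character(n_probes)
    fc <- numeric(n_probes)
    if (n_planted_probes > 0) {
      gene[seq_len(n_planted_probes)] <-
        rep(planted$gene_symbol, each = probes_per_gene)
      fc[seq_len(n_planted_probes)] <- rep(planted$log2_fc, each = probes_per_gene)
    }
    if (n_null > 0) {
      gene[(n_planted_probes + 1):n_probes] <-
        sprintf("GENE%05d", ceiling(seq_len(n_null) / probes_per_gene))
    }
    base <- rnorm(n_probes, baseline_mean, baseline_sd)
    logv <- matrix(rnorm(n_probes * length(samples), sd = noise_sd),
                   nrow = n_probes,
                   dimnames = list(probe_id, samples))
    logv <- logv + base
    logv[, sens_cols] <- logv[, sens_cols] + fc

    # detection grid: expressed probes are confidently present everywhere;
    # absent probes sit above the threshold in every sample
    detection <- matrix(runif(n_probes * length(samples), 0, detection_alpha / 2),
                        nrow = n_probes, dimnames = dimnames(logv))
    n_absent <- round(absent_frac * n_null)
    if (n_absent > 0) {
      absent_idx <- n_planted_probes + sample.int(n_null, n_absent)
      detection[absent_idx, ] <- runif(n_absent * length(samples),
                                       detection_alpha, 1)
    }
    list(expr = expr_matrix(2^logv, detection_p = detection, scale = "raw"),
         design = design,
         annotation = probe_gene_map(probe_id, gene))
  })
}

#' Simulate a linear kinetic fluorescence trace
#'
#' 31 readings at minutes 0..30: `signal = intercept + slope * minute`
#' plus Gaussian noise.
#'
#' @param slope True slope (signal units per minute).
#' @param intercept Baseline signal; default 0.
#' @param noise_sd Noise SD; default 0 (exact line).
#' @param seed Integer seed (only consulted when `noise_sd > 0`).
#' @return Tibble with columns `minute` and `signal`.
#' @export
simulate_kinetic_trace <- function(slope, intercept = 0, noise_sd = 0,
                                   seed = NULL) {
  stopifnot(noise_sd >= 0)
  minute <- 0:30
  noise <- if (noise_sd > 0) {
    if (is.null(seed)) stop_contract("`seed` is required when `noise_sd > 0`")
    withr::with_seed(seed, rnorm(length(minute), sd = noise_sd))
  } else {
    rep(0, length(minute))
  }
  tibble(minute = minute, signal = intercept + slope * minute + noise)
}
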