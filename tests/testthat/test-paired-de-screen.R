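test_that("detection filter keeps probes present in at least one sample", {
  v <- matrix(8, 3, 4, dimnames = list(c("allbad", "onegood", "allgood"),
                                       sprintf("s%d", 1:4)))
  dp <- rbind(rep(0.5, 4), c(0.5, 0.001, 0.8, 0.3), rep(0.0005, 4))
  x <- expr_matrix(v, detection_p = dp)
  kept <- suppressMessages(detection_filter(x, 0.01))
  expect_setequal(probe_ids(kept), c("onegood", "allgood"))

  expect_error(detection_filter(tiny_expr()), class = "chemoscreen_config_error")
})

test_that("the generator's planted detectable count is recovered exactly", {
  n_probes <- 2000
  absent_frac <- 0.3
  sim <- simulate_paired_experiment(n_probes = n_probes,
                                    absent_frac = absent_frac, seed = 8)
  kept <- suppressMessages(detection_filter(sim$expr, 0.01))
  expect_equal(nrow(kept$values), n_probes - round(absent_frac * n_probes))
})

test_that("log2 + quantile normalization equalizes sample distributions", {
  # identical columns: unchanged beyond the log2 transform
  v <- matrix(rep(c(2, 8, 32, 128), 2), ncol = 2,
              dimnames = list(sprintf("p%d", 1:4), c("a", "b")))
  norm <- normalize_log_quantile(expr_matrix(v, scale = "raw"))
  expect_equal(norm$values, log2(v))
  expect_equal(norm$scale, "log2")

  # columns that are permutations of each other end up with identical
  # sorted vectors
  v2 <- cbind(a = c(1, 4, 2, 16), b = c(16, 2, 4, 1))
  rownames(v2) <- sprintf("p%d", 1:4)
  norm2 <- normalize_log_quantile(expr_matrix(v2, scale = "raw"))
  expect_equal(unname(sort(norm2$values[, 1])),
               unname(sort(norm2$values[, 2])))

  # full quantile normalization equalizes column means
  sim <- withr::with_seed(21, matrix(2^rnorm(500 * 8, 8, 2), 500, 8,
                                     dimnames = list(sprintf("p%d", 1:500),
                                                     sprintf("s%d", 1:8))))
  norm3 <- normalize_log_quantile(expr_matrix(sim, scale = "raw"))
  cm <- colMeans(norm3$values)
  expect_lt(max(cm) - min(cm), 1e-12)

  expect_error(normalize_log_quantile(tiny_expr(scale = "log2")),
               class = "chemoscreen_contract_error")
  expect_error(
    normalize_log_quantile(tiny_expr(matrix(c(-1, 2, 3, 4), 2, 2), scale = "raw")),
    class = "chemoscreen_value_error")
})

test_that("moderation hyperparameters are recovered by moment matching", {
  # no excess dispersion: degenerate prior
  params <- estimate_moderation(rep(4, 100), residual_df = 8)
  expect_identical(params$prior_df, Inf)
  expect_equal(params$prior_var, 4)

  # parameter recovery: s^2 ~ sigma^2 chisq(d)/d, sigma^2 ~ s0^2 d0 / chisq(d0)
  d <- 8; d0 <- 4; s0 <- 1
  s2 <- withr::with_seed(17, {
    sigma2 <- s0 * d0 / rchisq(5000, d0)
    sigma2 * rchisq(5000, d) / d
  })
  fit <- estimate_moderation(s2, d)
  expect_gt(fit$prior_df, 2); expect_lt(fit$prior_df, 8)
  expect_gt(fit$prior_var, 0.8); expect_lt(fit$prior_var, 1.25)

  # independent cross-check against the established empirical-Bayes fit
  sq <- limma::squeezeVar(s2, df = d)
  expect_equal(fit$prior_df, sq$df.prior, tolerance = 0.05)
  expect_equal(fit$prior_var, sq$var.prior, tolerance = 0.01)

  expect_error(estimate_moderation(c(1, 2), 4), class = "chemoscreen_contract_error")
  expect_error(estimate_moderation(rep(0, 60), 4), class = "chemoscreen_degenerate_error")
})

test_that("moderated pair test reduces to the ordinary pooled t when prior_df = 0", {
  sim <- demo_paired(n_probes = 120, seed = 13)
  expr <- normalize_log_quantile(sim$expr)
  params0 <- structure(list(prior_df = 0, prior_var = 1),
                       class = "moderation_params")
  scr <- moderated_pair_test(expr, sim$design, params = params0,
                             annotation = sim$annotation)

  # hand-computed ordinary t for one probe and one pair
  v <- expr$values
  d <- sim$design$MM
  groups <- list(v["ILMN_000003", d$sensitive], v["ILMN_000003", d$resistant],
                 v["ILMN_000003", sim$design$MCL$sensitive],
                 v["ILMN_000003", sim$design$MCL$resistant])
  s2 <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0)) /
    sum(lengths(groups) - 1)
  t_ref <- (mean(groups[[1]]) - mean(groups[[2]])) / sqrt(s2 * (1 / 3 + 1 / 3))
  got <- scr$per_pair[scr$per_pair$probe_id == "ILMN_000003" &
                        scr$per_pair$pair == "MM", ]
  expect_equal(got$t, t_ref, tolerance = 1e-12)
  expect_equal(got$p, 2 * pt(-abs(t_ref), sum(lengths(groups) - 1)))
})

test_that("moderated variances are convex combinations and fold changes recover", {
  sim <- demo_paired(n_probes = 400, seed = 19)
  expr <- normalize_log_quantile(sim$expr)
  scr <- moderated_pair_test(expr, sim$design, annotation = sim$annotation)
  d0 <- scr$params$prior_df; s0 <- scr$params$prior_var

  # recompute raw pooled variances to check the convex-combination bound
  v <- expr$values
  groups <- unlist(lapply(sim$design, function(p)
    list(p$sensitive, p$resistant)), recursive = FALSE)
  ss <- rowSums(vapply(groups, function(ids) {
    g <- v[, ids, drop = FALSE]; rowSums((g - rowMeans(g))^2)
  }, numeric(nrow(v))))
  s2 <- ss / scr$residual_df
  v_mod <- if (is.infinite(d0)) rep(s0, length(s2)) else
    (d0 * s0 + scr$residual_df * s2) / (d0 + scr$residual_df)
  expect_true(all(v_mod >= pmin(s2, s0) - 1e-12 & v_mod <= pmax(s2, s0) + 1e-12))

  # planted genes: log2 fc = +/-1.5 recovered in both pairs within noise
  up <- scr$per_pair[scr$per_pair$probe_id == "ILMN_000001", ]
  expect_true(all(up$fold_change > 1.8 & up$fold_change < 4.5))
  rec <- scr$records[scr$records$probe_id == "ILMN_000001", ]
  expect_equal(rec$direction, "higher_in_sensitive")
  expect_equal(rec$gene_symbol, "UPGENE")

  # probe with identical values in all groups: fc = 1, direction none
  v2 <- v
  v2["ILMN_000010", ] <- 7.5
  scr2 <- moderated_pair_test(expr_matrix(v2, scale = "log2"), sim$design,
                              params = scr$params)
  flat <- scr2$per_pair[scr2$per_pair$probe_id == "ILMN_000010", ]
  expect_true(all(flat$fold_change == 1))
  expect_equal(
    scr2$records$direction[scr2$records$probe_id == "ILMN_000010"], "none")

  # design with a single replicate is rejected
  bad <- paired_design(design_pair("solo", "MM_S1", c("MM_R1", "MM_R2")))
  expect_error(moderated_pair_test(expr, bad), class = "chemoscreen_design_error")
})

test_that("moderated t converges to ordinary t as replication grows", {
  # with more replicates the data dominate the prior: the max |moderated -
  # ordinary| t discrepancy shrinks
  max_gap <- vapply(c(3, 6, 12), function(reps) {
    sim <- simulate_paired_experiment(n_probes = 150, replicates = reps, seed = 77)
    expr <- normalize_log_quantile(sim$expr)
    scr_mod <- moderated_pair_test(expr, sim$design)
    params0 <- structure(list(prior_df = 0, prior_var = 1),
                         class = "moderation_params")
    scr_ord <- moderated_pair_test(expr, sim$design, params = params0)
    max(abs(scr_mod$per_pair$t - scr_ord$per_pair$t))
  }, numeric(1))
  expect_true(all(diff(max_gap) < 0))
})

test_that("bh_fdr reproduces the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.037), 0.037)

  p <- withr::with_seed(4, runif(1000))
  q <- bh_fdr(p)
  expect_identical(q, bh_brute_force(p))
  # monotone nondecreasing in sorted-p order
  expect_false(is.unsorted(q[order(p)]))

  expect_error(bh_fdr(c(0.5, 0)), class = "chemoscreen_value_error")
  expect_error(bh_fdr(c(0.5, 1.2)), class = "chemoscreen_value_error")
})

test_that("the congruence filter enforces direction, threshold and significance", {
  sim <- demo_paired(n_probes = 300, seed = 23)
  expr <- normalize_log_quantile(sim$expr)
  scr <- moderated_pair_test(expr, sim$design, annotation = sim$annotation)

  res <- congruence_filter(scr)
  expect_true("UPGENE" %in% res$sensitivity$genes)
  expect_true("DOWNGENE" %in% res$resistance$genes)

  # directional incongruence: force opposite signs across pairs
  pp <- scr$per_pair
  pp$log2_fc[pp$probe_id == "ILMN_000001" & pp$pair == "MCL"] <- -1
  pp$fold_change <- 2^pp$log2_fc
  scr_bad <- scr; scr_bad$per_pair <- pp
  scr_bad$records$direction[scr_bad$records$probe_id == "ILMN_000001"] <- "none"
  res_bad <- congruence_filter(scr_bad)
  expect_false("UPGENE" %in% res_bad$sensitivity$genes)

  # a fold change at or below the threshold fails (strictly greater)
  pp2 <- scr$per_pair
  pp2$log2_fc[pp2$probe_id == "ILMN_000001"] <- log2(1.5)
  pp2$fold_change <- 2^pp2$log2_fc
  scr_edge <- scr; scr_edge$per_pair <- pp2
  expect_false("UPGENE" %in% congruence_filter(scr_edge)$sensitivity$genes)
  pp2$log2_fc[pp2$probe_id == "ILMN_000001"] <- log2(1.4)
  pp2$fold_change <- 2^pp2$log2_fc
  scr_edge$per_pair <- pp2
  expect_false("UPGENE" %in% congruence_filter(scr_edge)$sensitivity$genes)

  expect_error(congruence_filter(scr, fc_min = 1), class = "chemoscreen_value_error")
})

test_that("a planted 20 + 38 gene signature is recovered against 5000 nulls", {
  planted <- tibble::tibble(
    gene_symbol = c(sprintf("SENS%02d", 1:20), sprintf("RES%02d", 1:38)),
    log2_fc = c(rep(1.5, 20), rep(-1.5, 38)))
  sim <- simulate_paired_experiment(n_probes = 5058, planted = planted,
                                    absent_frac = 0, seed = 101)
  expr <- normalize_log_quantile(sim$expr)
  scr <- moderated_pair_test(expr, sim$design, annotation = sim$annotation)
  sets <- congruence_filter(scr)
  expect_setequal(sets$sensitivity$genes, sprintf("SENS%02d", 1:20))
  expect_setequal(sets$resistance$genes, sprintf("RES%02d", 1:38))
})
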