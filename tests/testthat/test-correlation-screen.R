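test_that("pearson_r matches its definitional brute-force oracle", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1)

  # brute-force summation oracle on a 60-point synthetic pair
  withr::with_seed(7, {
    x <- rnorm(60); y <- 0.4 * x + rnorm(60)
  })
  n <- length(x)
  r_brute <- (sum(x * y) - n * mean(x) * mean(y)) /
    sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  expect_equal(pearson_r(x, y), r_brute, tolerance = 1e-12)

  expect_error(pearson_r(c(1, 2), c(1, 2)), class = "chemoscreen_insufficient_data")
  expect_error(pearson_r(c(2, 2, 2), c(1, 2, 3)), class = "chemoscreen_degenerate_error")
})

test_that("t_from_r evaluates the exact r-to-t conversion", {
  expect_equal(t_from_r(0, 58), 0)
  # brute-force arithmetic on coefficients from the printed panel tables
  expect_equal(t_from_r(0.541833, 58), 0.541833 * sqrt(58) / sqrt(1 - 0.541833^2))
  expect_equal(t_from_r(0.541833, 58), 4.9096, tolerance = 1e-4)
  expect_equal(t_from_r(-0.49975, 58), -(0.49975 * sqrt(58) / sqrt(1 - 0.49975^2)))
  expect_true(all(sign(t_from_r(c(-0.3, 0.4), 58)) == c(-1, 1)))

  expect_warning(t_inf <- t_from_r(1, 10), class = "chemoscreen_infinite_statistic")
  expect_identical(t_inf, Inf)
  expect_error(t_from_r(1.2, 58), class = "chemoscreen_value_error")
})

test_that("p_from_t matches adaptive quadrature of the t density", {
  expect_equal(p_from_t(0, 5), 1)
  expect_equal(p_from_t(0, 58), 1)

  t_density <- function(x, df) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  grid <- expand.grid(t = c(0.5, 1.3, 2.1, 3.3, 4.9), df = c(3, 10, 58))
  for (i in seq_len(nrow(grid))) {
    quad <- 2 * stats::integrate(t_density, grid$t[i], Inf, df = grid$df[i],
                                 rel.tol = 1e-12)$value
    expect_equal(p_from_t(grid$t[i], grid$df[i]), quad, tolerance = 1e-10)
  }

  # infinite statistics are flagged at machine resolution, keeping p in (0, 1]
  expect_identical(p_from_t(Inf, 58), .Machine$double.xmin)
  expect_error(p_from_t(1, 0), class = "chemoscreen_contract_error")
})

test_that("p is monotone decreasing in |r| at fixed df", {
  r <- seq(0.05, 0.95, by = 0.05)
  p <- p_from_t(t_from_r(r, 58), 58)
  expect_true(all(diff(p) < 0))
  expect_identical(p_from_t(t_from_r(-0.4, 58), 58), p_from_t(t_from_r(0.4, 58), 58))
})

test_that("analytic P agrees with permutation P within Monte-Carlo error", {
  n <- 60; n_probes <- 8; n_perm <- 40000
  sim <- simulate_panel(n_probes = n_probes, n_samples = n,
                        planted = tibble::tibble(
                          probe_id = c("pl1", "pl2"), rho = c(0.3, -0.3)),
                        seed = 5)
  y <- sim$response$log10_gi50
  ys <- (y - mean(y)) / sd(y)
  v <- sim$expr$values
  xs <- (v - rowMeans(v)) / apply(v, 1, sd)
  r_obs <- as.vector(xs %*% ys) / (n - 1)
  p_analytic <- p_from_t(t_from_r(r_obs, n - 2), n - 2)

  perm <- withr::with_seed(99, replicate(n_perm, sample(ys)))
  r_perm <- (xs %*% perm) / (n - 1)                     # probes x n_perm
  p_perm <- rowMeans(abs(r_perm) >= abs(r_obs) - 1e-12)
  se <- sqrt(pmax(p_analytic * (1 - p_analytic), p_perm * (1 - p_perm)) / n_perm)
  check <- p_analytic > 1e-3
  expect_true(any(check))
  expect_true(all(abs(p_analytic - p_perm)[check] <= 3 * se[check] + 1 / n_perm))
})

test_that("the primary screen recovers planted probes and partitions by sign", {
  # single probe equal to the phenotype itself
  resp <- drug_response(c("a", "b", "c", "d"), 10^c(-6, -5.5, -5, -4.5))
  x <- tiny_expr(matrix(resp$log10_gi50, 1, 4), probes = "mimic",
                 samples = resp$sample_id)
  scr <- suppressWarnings(run_primary_screen(x, resp))
  expect_equal(scr$resistance$probe_id, "mimic")
  expect_equal(scr$resistance$r, 1)

  # planted +0.6 / -0.6 among 998 nulls
  sim <- simulate_panel(n_probes = 1000,
                        planted = tibble::tibble(probe_id = c("up_at", "dn_at"),
                                                 rho = c(0.6, -0.6)),
                        seed = 31)
  scr2 <- run_primary_screen(sim$expr, sim$response, alpha = 0.05)
  expect_true("up_at" %in% scr2$resistance$probe_id)
  expect_true("dn_at" %in% scr2$sensitivity$probe_id)
  expect_equal(nrow(scr2$records), 1000)

  # alpha = 1: every non-degenerate probe lands in exactly one list
  scr3 <- run_primary_screen(sim$expr, sim$response, alpha = 1)
  both <- c(scr3$resistance$probe_id, scr3$sensitivity$probe_id)
  expect_setequal(both, scr2$records$probe_id[scr2$records$r != 0])
  expect_equal(anyDuplicated(both), 0L)

  # ranking: descending |r|, ties broken by probe id
  expect_false(is.unsorted(rev(abs(scr2$resistance$r))))
  expect_equal(scr2$resistance$rank, seq_len(nrow(scr2$resistance)))
})

test_that("degenerate probes are skipped with reasons, not scored as r = 0", {
  resp <- drug_response(sprintf("s%d", 1:6), 10^seq(-6, -5, length.out = 6))
  v <- rbind(flat = rep(2, 6),
             live = seq(1, 2, length.out = 6),
             holey = c(1.4, NA, NA, NA, NA, 2))
  colnames(v) <- resp$sample_id
  scr <- run_primary_screen(expr_matrix(v), resp)
  expect_setequal(scr$skipped$probe_id, c("flat", "holey"))
  expect_equal(scr$skipped$reason[scr$skipped$probe_id == "flat"], "zero_variance")
  expect_equal(scr$skipped$reason[scr$skipped$probe_id == "holey"], "insufficient_data")
  expect_equal(scr$records$probe_id, "live")
})

test_that("collapse to unique transcripts dedupes and applies the conflict rule", {
  resp <- drug_response(sprintf("s%d", 1:20),
                        withr::with_seed(3, 10^runif(20, -7, -4)))
  y <- resp$log10_gi50
  v <- rbind("TIMP3-a" = y + 0.01 * seq_len(20),
             "TIMP3-b" = y + 0.012 * rev(seq_len(20)),
             "SPLIT-up" = y + 0.011 * seq_len(20),
             "SPLIT-dn" = -y + 0.013 * seq_len(20))
  colnames(v) <- resp$sample_id
  annot <- probe_gene_map(rownames(v), c("TIMP3", "TIMP3", "SPLIT", "SPLIT"))
  scr <- run_primary_screen(expr_matrix(v), resp)
  expect_message(collapse_unique_transcripts(scr, annot), "SPLIT")
  sets <- suppressMessages(collapse_unique_transcripts(scr, annot))
  expect_equal(sets$resistance$genes, "TIMP3")
  expect_equal(sets$conflicts, "SPLIT")
  expect_false("SPLIT" %in% c(sets$resistance$genes, sets$sensitivity$genes))

  # empty significant lists give empty signatures
  scr_empty <- run_primary_screen(expr_matrix(v), resp, alpha = 0)
  sets_empty <- collapse_unique_transcripts(scr_empty, annot)
  expect_length(sets_empty$sensitivity, 0)
  expect_length(sets_empty$resistance, 0)

  expect_error(collapse_unique_transcripts(scr, annot[1:3, ]),
               class = "chemoscreen_annotation_error")
})
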