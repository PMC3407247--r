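# Assay-level calculations: linear NADPH production rates from kinetic
# fluorescence traces, subtraction-based G6PD-specific activity,
# flow-cytometry cell-death normalization against matched untreated
# samples, and the geNorm-style reference-gene normalization factor.

#' Linear rate of a kinetic fluorescence trace
#'
#' Ordinary least-squares slope of signal versus time over the whole trace,
#' as used to quantify NADP+ to NADPH conversion from fluorescence read at
#' 1-minute intervals. No windowing or lag detection is applied.
#'
#' @param trace Data frame with numeric columns `minute` and `signal`
#'   (first two columns are used if unnamed); at least 3 time points, times
#'   strictly increasing.
#' @return The slope, in signal units per minute.
#' @examples
#' kinetic_rate(data.frame(minute = 0:30, signal = 5 + 2 * (0:30)))  # 2
#' @export
kinetic_rate <- function(trace) {
  trace <- as.data.frame(trace)
  if (!all(c("minute", "signal") %in% names(trace))) {
    if (ncol(trace) < 2) stop_contract("`trace` needs `minute` and `signal` columns")
    names(trace)[1:2] <- c("minute", "signal")
  }
  tm <- as.numeric(trace$minute)
  y <- as.numeric(trace$signal)
  if (length(tm) < 3) stop_contract("a kinetic trace needs at least 3 time points")
  if (any(diff(tm) <= 0)) stop_contract("times must be strictly increasing")
  if (any(!is.finite(tm)) || any(!is.finite(y))) stop_value("trace values must be finite")
  unname(coef(lm(y ~ tm))[2])
}

#' G6PD-specific enzymatic activity by subtraction
#'
#' Isolates glucose-6-phosphate-dehydrogenase activity by subtracting the
#' NADPH production rate driven by 6-phosphogluconate alone (downstream
#' 6PGD activity) from the rate driven by both substrates together. A
#' negative difference is returned as-is with a warning, not clamped.
#'
#' @param rate_both Rate(s) with both G6P and 6PG supplied.
#' @param rate_6pg Rate(s) with 6PG alone, from the same extract.
#' @return `rate_both - rate_6pg`, elementwise.
#' @export
g6pd_specific_activity <- function(rate_both, rate_6pg) {
  if (length(rate_both) != length(rate_6pg)) {
    stop_contract("`rate_both` and `rate_6pg` must have equal length")
  }
  out <- rate_both - rate_6pg
  if (any(out < 0)) {
    warn("negative G6PD-specific activity: 6PG-alone rate exceeds the combined rate",
         class = "chemoscreen_negative_activity")
  }
  out
}

#' Normalized percent cell death relative to a matched untreated sample
#'
#' Divides the treated sample's viable (DAPI-negative) fraction by that of
#' its matched untreated sample and converts to a percent-death scale on
#' which the untreated sample is exactly 0%:
#' `100 - 100 * treated / untreated`. A treated fraction exceeding the
#' untreated one yields a negative value, returned with a warning.
#'
#' @param treated_fraction Viable fraction(s) of treated sample(s), in
#'   `[0, 1]`.
#' @param untreated_fraction Viable fraction(s) of the matched untreated
#'   sample(s), in `(0, 1]`.
#' @return Normalized cell death in percent.
#' @examples
#' normalize_cell_death(0.40, 0.80)  # 50
#' @export
normalize_cell_death <- function(treated_fraction, untreated_fraction) {
  if (any(treated_fraction < 0 | treated_fraction > 1, na.rm = TRUE) ||
      any(untreated_fraction < 0 | untreated_fraction > 1, na.rm = TRUE)) {
    stop_value("viable fractions must lie in [0, 1]")
  }
  if (any(untreated_fraction == 0)) {
    stop_value("untreated viable fraction must be > 0")
  }
  out <- 100 - 100 * (treated_fraction / untreated_fraction)
  if (any(out < 0, na.rm = TRUE)) {
    warn("negative normalized cell death: treatment increased the viable fraction",
         class = "chemoscreen_negative_death")
  }
  out
}

#' geNorm-style reference normalization factor
#'
#' Geometric mean of the relative quantities of at least two endogenous
#' control genes, used to normalize qPCR target quantities for differential
#' loading.
#'
#' @param quantities Positive relative quantities of the reference genes.
#' @return The geometric mean, `exp(mean(log(quantities)))`.
#' @examples
#' genorm_factor(c(2, 8))  # 4
#' @export
genorm_factor <- function(quantities) {
  if (length(quantities) < 2) {
    stop_contract("a normalization factor needs at least 2 reference genes")
  }
  if (any(!is.finite(quantities)) || any(quantities <= 0)) {
    stop_value("reference quantities must be finite and > 0")
  }
  exp(mean(log(quantities)))
}
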